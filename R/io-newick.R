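#' Read a rooted gene or species tree from Newick text
#'
#' Parses a single Newick statement into an \code{ape} \code{phylo} object,
#' with validation beyond the parser: the statement must be
#' ";"-terminated, parentheses must balance, and leaf labels must be
#' unique. Internal node labels that are integers in [0, 100] are treated
#' as ultrafast-bootstrap-style support values (the IQ-TREE convention);
#' other labels are kept as plain names.
#'
#' @param text a Newick string, or NULL to read from \code{file}.
#' @param file path to a Newick file (used when \code{text} is NULL).
#' @return a rooted \code{phylo} object.
#' @seealso [nodeSupports()], [writeNewickTree()]
#' @export
#' @examples
#' tr <- readNewickTree("((A:1,B:1)95:1,C:2);")
#' nodeSupports(tr)
readNewickTree <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply Newick text or a file path")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("Newick parse error: empty input")
  if (!endsWith(text, ";"))
    stop("Newick parse error: statement not terminated by ';'")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' in input", depth))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: not a valid Newick statement")
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("Newick parse error: duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  tr
}

#' Write a tree as Newick text
#'
#' Branch lengths are written with six decimal places so that
#' write-then-read round-trips preserve them exactly at that precision;
#' internal node labels (supports) are preserved.
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; when NULL the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
writeNewickTree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Extract integer support values from internal node labels
#'
#' Internal node labels that are integers in [0, 100] are interpreted as
#' support values; any other label (names, empty strings) yields NA.
#'
#' @param tree a \code{phylo} object.
#' @return integer vector of length \code{tree$Nnode} (NA where no support).
#' @export
nodeSupports <- function(tree) {
  lab <- tree$node.label
  n <- tree$Nnode
  if (is.null(lab)) return(rep(NA_integer_, n))
  lab <- c(lab, rep("", n - length(lab)))
  sup <- suppressWarnings(as.numeric(lab))
  sup[!is.na(sup) & (sup != trunc(sup) | sup < 0 | sup > 100)] <- NA_real_
  as.integer(sup)
}
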