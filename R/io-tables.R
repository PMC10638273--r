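## Tabular readers/writers: HMMER domtblout, presence matrices, species maps.

#' Normalise a domain label
#'
#' Maps alternative profile names onto the package's canonical domain
#' vocabulary. In particular the C-terminal beta-hairpin shared by CBX and
#' RYBP/YAF proteins is reported by profile databases as \code{CBX7_C} or
#' \code{YAF2}; both are unified to \code{beta-HP}.
#'
#' @param domain character vector of domain names.
#' @return character vector of canonical names.
#' @export
normalizeDomainName <- function(domain) {
  aliases <- c(CBX7_C = "beta-HP", YAF2 = "beta-HP", "β-HP" = "beta-HP",
               Chromo = "chromo")
  hit <- domain %in% names(aliases)
  domain[hit] <- aliases[domain[hit]]
  domain
}

#' Parse HMMER 3 per-domain tabular output (domtblout)
#'
#' Reads \code{hmmsearch --domtblout} style tables into a data.frame of
#' domain hits. Targets are the searched protein sequences and queries the
#' domain profiles. Coordinates are taken from the envelope columns
#' (1-based inclusive); per-domain significance from the independent
#' E-value column; no filtering is applied at parse time.
#'
#' @param lines character vector of file lines, or NULL to read from
#'   \code{file}. Lines starting with \code{#} are comments.
#' @param file path to a domtblout file.
#' @param speciesOf function mapping a protein identifier to its species
#'   identifier. The default splits identifiers of the form
#'   \code{"species|protein"} and returns NA where there is no \code{"|"}.
#' @return data.frame with columns protein, species, domain, start, end,
#'   evalue, bits — one row per domain hit.
#' @export
parseDomtblout <- function(lines = NULL, file = NULL,
                           speciesOf = defaultSpeciesOf) {
  if (is.null(lines)) {
    if (is.null(file)) stop("supply lines or a file path")
    lines <- readLines(file, warn = FALSE)
  }
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 22L)
      stop(sprintf("domtblout format error at line %d: %d columns, expected >= 22",
                   i, length(fields)))
    num <- suppressWarnings(as.numeric(fields[c(13, 14, 20, 21)]))
    if (anyNA(num))
      stop(sprintf("domtblout format error at line %d: non-numeric E-value/score/coordinate",
                   i))
    out[[j]] <- data.frame(protein = fields[1], domain = normalizeDomainName(fields[4]),
                           start = as.integer(num[3]), end = as.integer(num[4]),
                           evalue = num[1], bits = num[2],
                           stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(protein = character(), domain = character(),
               start = integer(), end = integer(),
               evalue = numeric(), bits = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    if (any(hits$start > hits$end)) stop("domtblout format error: envelope start > end")
    if (any(hits$evalue <= 0)) stop("domtblout format error: E-value must be > 0")
  }
  hits$species <- if (nrow(hits)) vapply(hits$protein, speciesOf, character(1)) else character()
  hits[, c("protein", "species", "domain", "start", "end", "evalue", "bits")]
}

#' @rdname parseDomtblout
#' @param protein protein identifier(s).
#' @export
defaultSpeciesOf <- function(protein) {
  ifelse(grepl("|", protein, fixed = TRUE),
         sub("\\|.*$", "", protein), NA_character_)
}

#' Construct a PresenceMatrix
#'
#' @param states character matrix of cells in \{"1","0","P"\} with species
#'   rownames and subunit colnames.
#' @return a \linkS4class{PresenceMatrix}.
#' @export
PresenceMatrix <- function(states) {
  mode(states) <- "character"
  new("PresenceMatrix", states = states)
}

#' Read / write a three-state presence matrix as TSV
#'
#' The canonical layout: first column \code{species}, one column per
#' subunit, cells in \{1, 0, P\}. Unknown symbols are rejected with the
#' offending row and column named. \code{writePresenceMatrix} emits the
#' same layout so that write-then-read is the identity.
#'
#' @param file path to a TSV file.
#' @param text optional literal TSV text (overrides \code{file}).
#' @return a \linkS4class{PresenceMatrix}.
#' @export
readPresenceMatrix <- function(file = NULL, text = NULL) {
  df <- if (!is.null(text)) read.delim(text = text, check.names = FALSE,
                                       colClasses = "character")
        else read.delim(file, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("presence matrix needs a species column plus subunit columns")
  species <- df[[1]]
  if (anyDuplicated(species))
    stop("duplicate species row(s): ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- species
  bad <- which(!(m %in% validStates))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid cell value '%s' at species '%s', subunit '%s'",
                 m[bad[1]], rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  PresenceMatrix(m)
}

#' @rdname readPresenceMatrix
#' @param x a \linkS4class{PresenceMatrix}.
#' @export
writePresenceMatrix <- function(x, file) {
  df <- data.frame(species = speciesNames(x), presenceStates(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Construct a SpeciesMap
#'
#' @param species character vector of species identifiers.
#' @param group major eukaryotic group per species.
#' @param rootSide root side per species (constant within a group).
#' @return a \linkS4class{SpeciesMap}.
#' @export
SpeciesMap <- function(species, group, rootSide) {
  if (length(species) != length(group) || length(group) != length(rootSide))
    stop("species, group and rootSide must have equal length")
  for (sp in unique(species[duplicated(species)])) {
    if (length(unique(group[species == sp])) > 1L)
      stop(sprintf("species '%s' assigned to more than one group", sp))
  }
  for (g in unique(group)) {
    if (length(unique(rootSide[group == g])) > 1L)
      stop(sprintf("group '%s' assigned to both root sides", g))
  }
  first <- !duplicated(species)
  groupOf <- structure(group[first], names = species[first])
  gFirst <- !duplicated(group)
  sideOf <- structure(rootSide[gFirst], names = group[gFirst])
  new("SpeciesMap", groupOf = groupOf, sideOf = sideOf)
}

#' Read / write a species-to-group-to-root-side map as TSV
#'
#' Columns: \code{species}, \code{group}, \code{root_side}. A species may
#' not appear under two groups, nor a group under two root sides.
#'
#' @param file path to a TSV file.
#' @param text optional literal TSV text.
#' @return a \linkS4class{SpeciesMap}.
#' @export
readSpeciesMap <- function(file = NULL, text = NULL) {
  df <- if (!is.null(text)) read.delim(text = text, colClasses = "character")
        else read.delim(file, colClasses = "character")
  need <- c("species", "group", "root_side")
  if (!all(need %in% names(df)))
    stop("species map must have columns: ", paste(need, collapse = ", "))
  SpeciesMap(df$species, df$group, df$root_side)
}

#' @rdname readSpeciesMap
#' @param x a \linkS4class{SpeciesMap}.
#' @export
writeSpeciesMap <- function(x, file) {
  df <- data.frame(species = names(x@groupOf), group = unname(x@groupOf),
                   root_side = unname(x@sideOf[x@groupOf]),
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
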