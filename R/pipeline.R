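#' Run the full profiling pipeline
#'
#' End-to-end orchestrator: loads either a precomputed presence matrix or
#' a domtblout hit table (annotating and calling orthologs), optionally
#' labels a gene tree and delineates its orthologous groups with LECA
#' inference, categorizes species by complex completeness, summarizes,
#' computes pairwise phi co-occurrence with clustering, and writes every
#' stage artifact to \code{config$outDir}: \code{presence_matrix.tsv},
#' \code{categories.tsv}, \code{summary.json}, \code{phi_matrix.tsv},
#' \code{clustering_order.txt}, and (with a gene tree)
#' \code{groups.tsv}. All inputs are checked before any computation;
#' identical inputs and seed produce identical outputs.
#'
#' @param config a configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisible list with \code{matrix}, \code{report},
#'   \code{cooccurrence}, \code{groups} (or NULL), and \code{files}.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) stop("configuration error: not a PipelineConfig")
  inputs <- c(config$presenceMatrix, config$domtblout, config$speciesMap,
              config$geneTree, config$leafMeta)
  missing <- inputs[!vapply(inputs, file.exists, logical(1))]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (is.null(config$presenceMatrix) && is.null(config$domtblout))
    stop("configuration error: supply a presence matrix or a domtblout hit table")
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)

  if (!is.null(config$presenceMatrix)) {
    mat <- readPresenceMatrix(config$presenceMatrix)
  } else {
    hits <- parseDomtblout(file = config$domtblout)
    calls <- callOrthologs(hits, threshold = config$evalueThreshold)
    calls <- calls[calls$subunit %in% coreSubunits(), , drop = FALSE]
    mat <- assembleMatrix(calls)
  }

  groups <- NULL
  if (!is.null(config$geneTree)) {
    if (is.null(config$leafMeta))
      stop("configuration error: a gene tree needs leaf metadata")
    tree <- readNewickTree(file = config$geneTree)
    meta <- read.delim(config$leafMeta, colClasses = "character")
    labeled <- labelEvents(tree, meta, config$overlapThreshold)
    groups <- orthologousGroups(labeled)
    map <- if (!is.null(config$speciesMap)) readSpeciesMap(config$speciesMap) else NULL
    groups <- lapply(groups, function(g) {
      v <- delineationVerdict(g, meta, config$supportThreshold,
                              config$consistencyFraction)
      g$pass <- v$pass
      g$failed <- v$failed
      if (!is.null(map)) {
        l <- inferLeca(g, map, config$lecaMinGroups)
        g$leca <- l$leca
      }
      g
    })
  }

  cats <- categorizeSpecies(mat)
  report <- summarizeCategories(cats)
  co <- suppressWarnings(
    cooccurrence(mat, putativeHandling = config$putativeHandling))

  files <- c(presence_matrix = file.path(config$outDir, "presence_matrix.tsv"),
             categories = file.path(config$outDir, "categories.tsv"),
             summary = file.path(config$outDir, "summary.json"),
             phi = file.path(config$outDir, "phi_matrix.tsv"),
             order = file.path(config$outDir, "clustering_order.txt"))
  writePresenceMatrix(mat, files[["presence_matrix"]])
  write.table(data.frame(species = names(cats), category = unname(cats)),
              files[["categories"]], sep = "\t", quote = FALSE, row.names = FALSE)
  avg <- co@averages
  summary <- list(
    total = report@total,
    counts = as.list(categoryCounts(report)),
    percentages = as.list(categoryPercentages(report)),
    singleComplexPercent = singleComplexPercent(report),
    uncoupledPercent = uncoupledPercent(report),
    phiAverages = list(intraPRC1 = avg[["intraPRC1"]],
                       intraPRC2 = avg[["intraPRC2"]],
                       inter = avg[["inter"]]),
    thresholds = config[c("evalueThreshold", "supportThreshold",
                          "consistencyFraction", "overlapThreshold",
                          "lecaMinGroups", "putativeHandling", "seed")])
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  phiDf <- data.frame(subunit = rownames(phiMatrix(co)), phiMatrix(co),
                      check.names = FALSE)
  write.table(phiDf, files[["phi"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(co@order, files[["order"]])
  if (!is.null(groups)) {
    gdf <- do.call(rbind, lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      data.frame(group = i, members = paste(g$members, collapse = ","),
                 support = g$support, pass = g$pass,
                 failed = paste(g$failed, collapse = ";"),
                 leca = if (!is.null(g$leca)) g$leca else NA,
                 stringsAsFactors = FALSE)
    }))
    files <- c(files, groups = file.path(config$outDir, "groups.tsv"))
    write.table(gdf, files[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(matrix = mat, report = report, cooccurrence = co,
                 groups = groups, files = files))
}
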