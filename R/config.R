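#' Pipeline configuration
#'
#' Assembles and validates the full set of tunable thresholds plus input/
#' output paths. Every threshold is overridable; the defaults are: 1e-5
#' per-domain E-value cutoff (the classical homology-search significance
#' convention), support threshold 90 (strict: a group passes only with
#' support > 90), consistency fraction 0.8, species-overlap threshold 0
#' (any shared species implies a duplication), and a LECA rule of both
#' root sides plus at least 3 distinct major groups.
#'
#' @param evalueThreshold per-domain E-value cutoff (> 0).
#' @param supportThreshold integer in [0, 100].
#' @param consistencyFraction fraction in [0, 1].
#' @param overlapThreshold fraction in [0, 1].
#' @param lecaMinGroups integer >= 1.
#' @param putativeHandling "pairwise" or "listwise" putative exclusion.
#' @param seed integer random seed.
#' @param presenceMatrix path to a precomputed presence-matrix TSV (or NULL).
#' @param domtblout path to a domtblout hit table (or NULL).
#' @param speciesMap path to a species-map TSV (or NULL).
#' @param geneTree path to a Newick gene tree (or NULL).
#' @param leafMeta path to a leaf-metadata TSV (or NULL).
#' @param outDir output directory.
#' @return validated configuration list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(evalueThreshold = 1e-5, supportThreshold = 90,
                           consistencyFraction = 0.8, overlapThreshold = 0,
                           lecaMinGroups = 3L,
                           putativeHandling = c("pairwise", "listwise"),
                           seed = 1L, presenceMatrix = NULL, domtblout = NULL,
                           speciesMap = NULL, geneTree = NULL, leafMeta = NULL,
                           outDir = ".") {
  putativeHandling <- match.arg(putativeHandling)
  if (evalueThreshold <= 0) stop("evalueThreshold must be > 0")
  if (supportThreshold < 0 || supportThreshold > 100)
    stop("supportThreshold must lie in [0, 100]")
  if (consistencyFraction < 0 || consistencyFraction > 1)
    stop("consistencyFraction must lie in [0, 1]")
  if (overlapThreshold < 0 || overlapThreshold > 1)
    stop("overlapThreshold must lie in [0, 1]")
  if (lecaMinGroups < 1) stop("lecaMinGroups must be >= 1")
  structure(list(evalueThreshold = evalueThreshold,
                 supportThreshold = supportThreshold,
                 consistencyFraction = consistencyFraction,
                 overlapThreshold = overlapThreshold,
                 lecaMinGroups = as.integer(lecaMinGroups),
                 putativeHandling = putativeHandling,
                 seed = as.integer(seed),
                 presenceMatrix = presenceMatrix, domtblout = domtblout,
                 speciesMap = speciesMap, geneTree = geneTree,
                 leafMeta = leafMeta, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any argument of [pipelineConfig()]; unset keys keep
#' their defaults.
#'
#' @param file path to a YAML configuration file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("configuration error: no such file: ", file)
  vals <- yaml::read_yaml(file)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}
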