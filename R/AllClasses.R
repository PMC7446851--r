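#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @useDynLib topoflex, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

ATOM_COLUMNS <- c("chain", "resno", "resid", "elety", "element",
                  "x", "y", "z", "b")
HEAVY_ELEMENTS <- c("C", "N", "O", "P")

#' StructureSet: parsed atomic records grouped by chain
#'
#' Container for the atoms of one source (typically one PDB file). Atoms are
#' stored in file order in a single data.frame with columns
#' \code{chain, resno, resid, elety, element, x, y, z, b} (coordinates in
#' Angstrom, B-factors in Angstrom squared). Chains are identified by their
#' chain identifier; chain order follows first appearance in the file.
#'
#' @slot atoms data.frame of atomic records in file order.
#' @slot source character scalar labelling the origin (file path or synthetic
#'   generator tag).
#' @export
setClass("StructureSet",
  representation(atoms = "data.frame", source = "character"),
  prototype(atoms = data.frame(), source = NA_character_))

setValidity("StructureSet", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)
  missing_cols <- setdiff(ATOM_COLUMNS, names(a))
  if (length(missing_cols))
    return(paste("atoms is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all atom coordinates must be finite")
  TRUE
})

#' FeatureConfig: hyperparameters of the topological featurization
#'
#' Defines how each C1' neighbourhood is turned into a feature vector: the
#' Euclidean cut-off distance E selecting atoms around the centre, the ratio
#' F/E fixing the filtration interval [0, F], the bin size f that discretizes
#' [0, F] into N = round(F/f) bins, the chemical elements considered, and the
#' homology dimensions whose barcodes are binned.
#'
#' @slot cutoff Euclidean cut-off distance E in Angstrom (> 0).
#' @slot feRatio ratio F/E in (0, 1]; the filtration runs over [0, E * feRatio].
#' @slot binSize requested bin width f in Angstrom; the effective width is
#'   F/N with N = round(F/f) and must lie within 25 percent of f.
#' @slot elements ordered subset of C, N, O, P.
#' @slot dims ordered subset of homology dimensions 0, 1, 2 (ascending).
#' @export
setClass("FeatureConfig",
  representation(cutoff = "numeric", feRatio = "numeric",
                 binSize = "numeric", elements = "character",
                 dims = "integer"))

setValidity("FeatureConfig", function(object) {
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0)
    return("cutoff must be a single positive number (Angstrom)")
  if (length(object@feRatio) != 1L || object@feRatio <= 0 ||
      object@feRatio > 1)
    return("feRatio must lie in (0, 1]")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    return("binSize must be positive")
  if (!length(object@elements) ||
      !all(object@elements %in% HEAVY_ELEMENTS) ||
      anyDuplicated(object@elements))
    return("elements must be a non-empty duplicate-free subset of C,N,O,P")
  if (!length(object@dims) || !all(object@dims %in% 0:2) ||
      is.unsorted(object@dims, strictly = TRUE))
    return("dims must be a strictly increasing subset of 0,1,2")
  Fmax <- object@cutoff * object@feRatio
  N <- max(1L, as.integer(round(Fmax / object@binSize)))
  eff <- Fmax / N
  if (abs(eff - object@binSize) > 0.25 * object@binSize)
    return(sprintf(
      "effective bin width %.4g deviates more than 25%% from binSize %.4g",
      eff, object@binSize))
  TRUE
})

#' GeneratorConfig: parameters of the synthetic RNA-like structure generator
#'
#' The generator places one C1' atom per nucleotide on a regular helix and
#' surrounds it with a fixed heavy-atom template (counts per element), jittered
#' by isotropic Gaussian noise. Ground-truth B-factors follow a weighted
#' contact-number law: raw B = a - b * (heavy atoms within radius r) plus
#' Gaussian noise of standard deviation sigma, floored at a small positive
#' value, so flexibility decreases with local packing density.
#'
#' @slot nChains number of chains to generate.
#' @slot nucleotides integer range (min, max) of nucleotides per chain.
#' @slot rise helix rise per nucleotide along the chain axis, Angstrom.
#' @slot radius helix radius around the axis, Angstrom.
#' @slot twist twist per nucleotide, degrees.
#' @slot bendSd per-step random bending of the chain axis (sd of the
#'   direction perturbation); 0 gives a straight helix.
#' @slot confinement strength of the pull of the axis back toward the
#'   origin, folding the chain into a compact tertiary-structure-like blob
#'   with spatially varying packing density; 0 disables folding.
#' @slot template named integer vector of heavy-atom counts per nucleotide
#'   (C, N, O, P); C must be at least 1 (the C1' atom itself counts as one C).
#' @slot jitterSd isotropic placement noise for template atoms, Angstrom.
#' @slot bfactorBase intercept a of the contact-number law, Angstrom squared.
#' @slot bfactorSlope slope b of the contact-number law.
#' @slot interactionRadius contact radius r, Angstrom.
#' @slot noiseSd standard deviation sigma of the additive B-factor noise.
#' @slot seed integer seed making the generated set a pure function of the
#'   configuration.
#' @export
setClass("GeneratorConfig",
  representation(nChains = "integer", nucleotides = "integer",
                 rise = "numeric", radius = "numeric", twist = "numeric",
                 bendSd = "numeric", confinement = "numeric",
                 template = "integer", jitterSd = "numeric",
                 bfactorBase = "numeric", bfactorSlope = "numeric",
                 interactionRadius = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@nChains < 1L) return("nChains must be >= 1")
  if (length(object@nucleotides) != 2L ||
      any(object@nucleotides < 3L) ||
      object@nucleotides[1] > object@nucleotides[2])
    return("nucleotides must be an increasing range with minimum >= 3")
  tpl <- object@template
  if (!all(HEAVY_ELEMENTS %in% names(tpl)))
    return("template must name counts for C, N, O and P")
  if (tpl[["C"]] < 1L) return("template must contain at least one C")
  if (any(tpl < 0L)) return("template counts must be non-negative")
  if (object@interactionRadius <= 0) return("interactionRadius must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!is.finite(object@seed)) return("seed is mandatory")
  TRUE
})

#' ModelSpec: a regression family plus its hyperparameters
#'
#' @slot family one of ridge, lasso, rf, xgboost, svr, ann.
#' @slot hyperparameters named list of family-specific settings (see
#'   \code{\link{modelSpec}} for the keys and defaults).
#' @slot seed integer seed used by stochastic trainers (rf, xgboost, ann).
#' @export
setClass("ModelSpec",
  representation(family = "character", hyperparameters = "list",
                 seed = "integer"))

MODEL_FAMILIES <- c("ridge", "lasso", "rf", "xgboost", "svr", "ann")

setValidity("ModelSpec", function(object) {
  if (length(object@family) != 1L || !object@family %in% MODEL_FAMILIES)
    return(paste("family must be one of:",
                 paste(MODEL_FAMILIES, collapse = ", ")))
  hp <- object@hyperparameters
  required <- switch(object@family,
    ridge = "alpha", lasso = "alpha",
    rf = c("n_trees", "min_samples_leaf"),
    xgboost = c("n_trees", "max_depth"),
    svr = c("gamma", "cost", "epsilon"),
    ann = c("n_hidden_layers", "nodes_per_layer", "dropout", "epochs"))
  missing_keys <- setdiff(required, names(hp))
  if (length(missing_keys))
    return(paste0(object@family, " spec is missing hyperparameters: ",
                  paste(missing_keys, collapse = ", ")))
  num <- vapply(hp[required], function(v) is.numeric(v) && all(v >= 0),
                logical(1))
  if (!all(num)) return("all numeric hyperparameters must be non-negative")
  TRUE
})

#' TopoDataset: a featurized structure set
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"counts"} holds the p x n integer matrix of binned topological
#' features (features in rows, samples in columns); \code{colData} carries
#' \code{sample_id}, \code{chain}, \code{resno} and the normalized B-factor
#' target \code{y}; \code{rowData} describes each feature's element, homology
#' dimension, bin index and filtration grid point; the generating
#' \linkS4class{FeatureConfig} sits in \code{metadata(x)$config}.
#'
#' @export
setClass("TopoDataset", contains = "SummarizedExperiment")

setValidity("TopoDataset", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("TopoDataset requires a 'counts' assay")
  cd <- colData(object)
  need <- c("sample_id", "chain", "y")
  missing_cols <- setdiff(need, names(cd))
  if (length(missing_cols))
    return(paste("colData is missing:", paste(missing_cols, collapse = ", ")))
  if (any(assay(object, "counts") < 0))
    return("feature counts must be non-negative")
  TRUE
})
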