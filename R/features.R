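#' @include AllGenerics.R persistence.R targets.R structure-io.R
NULL

#' Construct a FeatureConfig
#'
#' @param cutoff Euclidean cut-off E around each C1' atom, Angstrom.
#' @param feRatio ratio F/E in (0, 1]; the filtration interval is [0, E * feRatio].
#' @param binSize bin width f, Angstrom; the number of bins is
#'   N = round(F/f) (at least 1), so the grid points sit at kF/N and the
#'   effective width F/N may differ slightly from f (it must stay within 25
#'   percent).
#' @param elements elements featurized separately, in the fixed order C, N,
#'   O, P.
#' @param dims homology dimensions whose barcodes are binned (ascending).
#' @return a validated \linkS4class{FeatureConfig}.
#' @examples
#' cfg <- FeatureConfig(cutoff = 15, feRatio = 0.5, binSize = 0.5)
#' nBins(cfg)      # 15
#' nFeatures(cfg)  # 4 elements * 2 dims * 15 bins = 120
#' @export
FeatureConfig <- function(cutoff = 15, feRatio = 0.5, binSize = 0.5,
                          elements = c("C", "N", "O", "P"),
                          dims = c(0L, 1L)) {
  elements <- HEAVY_ELEMENTS[HEAVY_ELEMENTS %in% elements]
  new("FeatureConfig", cutoff = as.numeric(cutoff),
      feRatio = as.numeric(feRatio), binSize = as.numeric(binSize),
      elements = elements, dims = sort(as.integer(dims)))
}

#' @describeIn filtrationMax filtration bound F = cutoff * feRatio
#' @export
setMethod("filtrationMax", "FeatureConfig",
          function(x) x@cutoff * x@feRatio)

#' @describeIn nBins N = round(F / binSize), at least 1
#' @export
setMethod("nBins", "FeatureConfig", function(x)
  max(1L, as.integer(round(filtrationMax(x) / x@binSize))))

#' @describeIn nFeatures p = |elements| * |dims| * N
#' @export
setMethod("nFeatures", "FeatureConfig", function(x)
  length(x@elements) * length(x@dims) * nBins(x))

setMethod("show", "FeatureConfig", function(object) {
  cat(sprintf(
    "FeatureConfig: E = %g A, F/E = %g (F = %g A), f = %g A (N = %d)\n",
    object@cutoff, object@feRatio, filtrationMax(object), object@binSize,
    nBins(object)))
  cat("elements:", paste(object@elements, collapse = ","),
      " dims:", paste(object@dims, collapse = ","),
      " p =", nFeatures(object), "\n")
  invisible(NULL)
})

#' Extract the element-specific local point cloud around a sample atom
#'
#' Collects the coordinates of all atoms of the given element within
#' Euclidean distance E of the centre, and appends the centre's own
#' coordinates: the central C1' atom is always part of every element's cloud
#' (without duplication when the element is C and the centre selects itself).
#'
#' @param heavyAtoms data.frame of the chain's heavy atoms.
#' @param center single-row data.frame, the sample (C1') atom.
#' @param cutoff Euclidean cut-off E > 0, Angstrom.
#' @param element one of C, N, O, P.
#' @return m x 3 coordinate matrix (m >= 1; the centre alone is legal).
#' @export
extractLocalRegion <- function(heavyAtoms, center, cutoff, element) {
  stopifnot(cutoff > 0, element %in% HEAVY_ELEMENTS, nrow(center) == 1L)
  cxyz <- c(center$x, center$y, center$z)
  sel <- heavyAtoms[heavyAtoms$element == element, , drop = FALSE]
  if (nrow(sel)) {
    d2 <- (sel$x - cxyz[1])^2 + (sel$y - cxyz[2])^2 + (sel$z - cxyz[3])^2
    sel <- sel[d2 <= cutoff^2, , drop = FALSE]
  }
  pts <- as.matrix(sel[, c("x", "y", "z"), drop = FALSE])
  # append the centre unless it is already one of the selected atoms
  already <- nrow(pts) > 0 &&
    any(pts[, 1] == cxyz[1] & pts[, 2] == cxyz[2] & pts[, 3] == cxyz[3])
  if (!already) pts <- rbind(pts, cxyz)
  dimnames(pts) <- NULL
  pts
}

#' Bin a barcode into an integer feature vector
#'
#' Divides the filtration interval [0, F] into N bins with grid points at
#' kF/N (k = 1..N) and counts, for each grid point, the bars alive there:
#' component k is the number of bars (b, d) with b <= kF/N <= d, both ends
#' inclusive. An infinite death satisfies the right inequality at every grid
#' point.
#'
#' @param bars data.frame with columns \code{birth} and \code{death}
#'   (one homology dimension; may have zero rows).
#' @param maxFiltration filtration bound F > 0.
#' @param nbins number of bins N >= 1.
#' @return integer vector of length \code{nbins}.
#' @export
binBarcode <- function(bars, maxFiltration, nbins) {
  stopifnot(maxFiltration > 0, nbins >= 1L)
  grid <- seq_len(nbins) * maxFiltration / nbins
  if (is.null(bars) || nrow(bars) == 0L) return(integer(nbins))
  vapply(grid, function(g)
    sum(bars$birth <= g & g <= bars$death), integer(1))
}

#' Topological feature vector of one sample atom
#'
#' For each configured element (fixed order C, N, O, P) and each homology
#' dimension (ascending), extracts the local region, computes its
#' Vietoris-Rips barcode up to the largest configured dimension, bins each
#' dimension's barcode, and concatenates the blocks element-major,
#' dimension-minor.
#'
#' @param heavyAtoms data.frame of the chain's heavy atoms.
#' @param center single-row data.frame, the sample (C1') atom.
#' @param config a \linkS4class{FeatureConfig}.
#' @return integer vector of length \code{nFeatures(config)}.
#' @export
featurizeSample <- function(heavyAtoms, center, config) {
  stopifnot(is(config, "FeatureConfig"))
  Fmax <- filtrationMax(config)
  N <- nBins(config)
  maxd <- max(config@dims)
  blocks <- lapply(config@elements, function(el) {
    cloud <- extractLocalRegion(heavyAtoms, center, config@cutoff, el)
    bars <- if (nrow(cloud) == 1L) {
      # a lone centre has one infinite component and no higher features
      data.frame(dim = 0L, birth = 0, death = Inf)
    } else {
      ripsPersistence(cloud, Fmax, maxd)
    }
    unlist(lapply(config@dims, function(d)
      binBarcode(bars[bars$dim == d, , drop = FALSE], Fmax, N)))
  })
  out <- unlist(blocks)
  storage.mode(out) <- "integer"
  out
}

.feature_names <- function(config) {
  N <- nBins(config)
  unlist(lapply(config@elements, function(el)
    unlist(lapply(config@dims, function(d)
      sprintf("%s_dim%d_bin%d", el, d, seq_len(N))))))
}

#' Build a featurized dataset from parsed structures
#'
#' Runs the full featurization pipeline per chain: locate the C1' sample
#' atoms, remove raw B-factor outliers with the median rule, z-normalize the
#' retained B-factors per chain, and compute each retained sample's
#' topological feature vector from the chain's heavy atoms. Chains with
#' fewer than 3 sample atoms, no sample atoms at all, or zero B-factor
#' variance are skipped with a warning. Rows are grouped by chain in input
#' order.
#'
#' @param structures a \linkS4class{StructureSet} or list of them.
#' @param config a \linkS4class{FeatureConfig}.
#' @param outlierThreshold modified z-score cutoff passed to
#'   \code{\link{removeOutliersMedian}}.
#' @return a \linkS4class{TopoDataset}.
#' @export
buildDataset <- function(structures, config, outlierThreshold = 3.5) {
  stopifnot(is(config, "FeatureConfig"))
  if (is(structures, "StructureSet")) structures <- list(structures)
  p <- nFeatures(config)
  Xrows <- list(); ys <- numeric(0)
  chains <- character(0); resnos <- integer(0); ids <- character(0)
  for (ss in structures) {
    for (cid in chainIds(ss)) {
      atoms <- chainAtoms(ss, cid)
      heavy <- selectHeavyAtoms(atoms)
      samples <- findSampleAtoms(atoms)
      if (nrow(samples) == 0L) {
        warning("chain ", cid, ": no C1' sample atoms; skipped")
        next
      }
      if (nrow(samples) < 3L) {
        warning("chain ", cid, ": fewer than 3 sample atoms; skipped")
        next
      }
      tg <- tryCatch(.chain_targets(samples$b, outlierThreshold),
                     error = function(e) {
                       warning("chain ", cid, ": ", conditionMessage(e),
                               "; skipped")
                       NULL
                     })
      if (is.null(tg)) next
      kept <- samples[tg$mask, , drop = FALSE]
      for (s in seq_len(nrow(kept))) {
        Xrows[[length(Xrows) + 1L]] <-
          featurizeSample(heavy, kept[s, , drop = FALSE], config)
      }
      ys <- c(ys, tg$values)
      chains <- c(chains, rep(cid, nrow(kept)))
      resnos <- c(resnos, kept$resno)
      ids <- c(ids, paste0(cid, ":", kept$resno))
    }
  }
  if (!length(Xrows)) stop("no usable chains; cannot build a dataset")
  X <- do.call(rbind, Xrows)
  colnames(X) <- .feature_names(config)
  N <- nBins(config)
  rd <- S4Vectors::DataFrame(
    element = rep(config@elements, each = length(config@dims) * N),
    dim = rep(rep(config@dims, each = N), times = length(config@elements)),
    bin = rep(seq_len(N),
              times = length(config@elements) * length(config@dims)))
  rd$grid <- rd$bin * filtrationMax(config) / N
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(X)),
    colData = S4Vectors::DataFrame(sample_id = ids, chain = chains,
                                   resno = resnos, y = ys,
                                   row.names = ids),
    rowData = rd)
  S4Vectors::metadata(se)$config <- config
  new("TopoDataset", se)
}

#' @describeIn featureMatrix samples-in-rows view of the counts assay
#' @export
setMethod("featureMatrix", "TopoDataset", function(x)
  t(SummarizedExperiment::assay(x, "counts")))

#' @describeIn targets the normalized B-factor of each sample
#' @export
setMethod("targets", "TopoDataset", function(x) colData(x)$y)

#' @describeIn chainLabels the chain of each sample
#' @export
setMethod("chainLabels", "TopoDataset", function(x)
  as.character(colData(x)$chain))

#' @describeIn featureConfig the FeatureConfig stored in the metadata
#' @export
setMethod("featureConfig", "TopoDataset", function(x)
  S4Vectors::metadata(x)$config)

setMethod("show", "TopoDataset", function(object) {
  cat("TopoDataset:", ncol(object), "samples x", nrow(object), "features,",
      length(unique(chainLabels(object))), "chain(s)\n")
  cfg <- featureConfig(object)
  if (!is.null(cfg)) show(cfg)
  invisible(NULL)
})

#' Write a TopoDataset to CSV (with a YAML config sidecar)
#'
#' The CSV carries one row per sample: \code{sample_id}, \code{chain},
#' \code{resno}, \code{y}, then one column per feature named
#' \code{ELEMENT_dimD_binK}. The featurization parameters go to
#' \code{<path>.yaml}.
#'
#' @param x a \linkS4class{TopoDataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(x, path) {
  stopifnot(is(x, "TopoDataset"))
  cd <- as.data.frame(colData(x))
  out <- cbind(cd[, c("sample_id", "chain", "resno", "y")],
               as.data.frame(featureMatrix(x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  cfg <- featureConfig(x)
  side <- list(cutoff = cfg@cutoff, fe_ratio = cfg@feRatio,
               bin_size = cfg@binSize,
               elements = as.list(cfg@elements),
               dims = as.list(cfg@dims))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a TopoDataset written by \code{\link{writeDataset}}
#' @param path CSV path (the \code{<path>.yaml} sidecar must sit beside it).
#' @return a \linkS4class{TopoDataset}.
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  cfg <- FeatureConfig(cutoff = side$cutoff, feRatio = side$fe_ratio,
                       binSize = side$bin_size,
                       elements = unlist(side$elements),
                       dims = unlist(side$dims))
  meta <- c("sample_id", "chain", "resno", "y")
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(X)),
    colData = S4Vectors::DataFrame(sample_id = df$sample_id,
                                   chain = as.character(df$chain),
                                   resno = df$resno, y = df$y,
                                   row.names = df$sample_id))
  S4Vectors::metadata(se)$config <- cfg
  new("TopoDataset", se)
}
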