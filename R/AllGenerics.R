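#' @include AllClasses.R
NULL

#' Chain identifiers of a StructureSet
#' @param x a \linkS4class{StructureSet}.
#' @return character vector of chain ids in order of first appearance.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Atoms of one chain
#' @param x a \linkS4class{StructureSet}.
#' @param id chain identifier.
#' @return data.frame of the chain's atoms in file order.
#' @export
setGeneric("chainAtoms", function(x, id) standardGeneric("chainAtoms"))

#' Number of atoms
#' @param x a \linkS4class{StructureSet}.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Filtration upper bound F = E * (F/E ratio)
#' @param x a \linkS4class{FeatureConfig}.
#' @return numeric, Angstrom.
#' @export
setGeneric("filtrationMax", function(x) standardGeneric("filtrationMax"))

#' Number of filtration bins N = round(F / f)
#' @param x a \linkS4class{FeatureConfig}.
#' @return integer >= 1.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Feature vector length p = |elements| * |dims| * N
#' @param x a \linkS4class{FeatureConfig}.
#' @return integer.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Sample-by-feature matrix of a TopoDataset
#' @param x a \linkS4class{TopoDataset}.
#' @return n x p numeric matrix (samples in rows), column names as in rowData.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Normalized B-factor targets of a TopoDataset
#' @param x a \linkS4class{TopoDataset}.
#' @return numeric vector aligned with \code{featureMatrix(x)} rows.
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' Chain label of each sample
#' @param x a \linkS4class{TopoDataset}.
#' @return character vector aligned with \code{featureMatrix(x)} rows.
#' @export
setGeneric("chainLabels", function(x) standardGeneric("chainLabels"))

#' Featurization configuration of a TopoDataset
#' @param x a \linkS4class{TopoDataset}.
#' @return the \linkS4class{FeatureConfig} used to build it.
#' @export
setGeneric("featureConfig", function(x) standardGeneric("featureConfig"))
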