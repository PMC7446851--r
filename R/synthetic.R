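#' @include structure-io.R learning.R
NULL

#' Construct a GeneratorConfig
#'
#' Defaults describe a small RNA-like study set: 8 chains of 30-60
#' nucleotides. Each chain is an A-form-like helical tube (rise 2.81
#' Angstrom per nucleotide, radius 9 Angstrom, twist 32 degrees) wound
#' around a confined random-walk axis (bendSd 0.3, confinement 0.15), so
#' the chain folds back on itself like a tertiary structure and the local
#' packing density genuinely varies along the chain. The heavy-atom
#' template holds 9 C, 4 N, 7 O and 1 P per nucleotide (a ribonucleotide's
#' stoichiometry, one C being the C1' itself), placed with 0.3 Angstrom
#' jitter. Ground-truth B-factors follow the contact-number law
#' B = 110 - 0.1 * (heavy atoms within 15 Angstrom) + N(0, noiseSd),
#' floored at 0.01: flexibility decreases with local packing, so termini
#' and loosely packed stretches are the most flexible.
#'
#' @param nChains number of chains.
#' @param nucleotides length-2 range of nucleotides per chain.
#' @param rise,radius,twist helix geometry (Angstrom, Angstrom, degrees).
#' @param bendSd,confinement folding of the chain axis (0/0 = straight
#'   helix).
#' @param template named counts of heavy atoms per nucleotide.
#' @param jitterSd placement noise sd, Angstrom.
#' @param bfactorBase,bfactorSlope,interactionRadius,noiseSd parameters of
#'   the contact-number B-factor law.
#' @param seed mandatory integer root seed.
#' @return a validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(nChains = 8L, nucleotides = c(30L, 60L),
                            rise = 2.81, radius = 9, twist = 32,
                            bendSd = 0.3, confinement = 0.15,
                            template = c(C = 9L, N = 4L, O = 7L, P = 1L),
                            jitterSd = 0.3, bfactorBase = 110,
                            bfactorSlope = 0.1, interactionRadius = 15,
                            noiseSd = 2.0, seed = 1L) {
  new("GeneratorConfig", nChains = as.integer(nChains),
      nucleotides = as.integer(nucleotides), rise = as.numeric(rise),
      radius = as.numeric(radius), twist = as.numeric(twist),
      bendSd = as.numeric(bendSd), confinement = as.numeric(confinement),
      template = vapply(template, as.integer, integer(1)),
      jitterSd = as.numeric(jitterSd),
      bfactorBase = as.numeric(bfactorBase),
      bfactorSlope = as.numeric(bfactorSlope),
      interactionRadius = as.numeric(interactionRadius),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# atom names for the per-nucleotide heavy-atom template (C1' first)
.template_names <- function(tpl) {
  cn <- c("C1'", "C2'", "C3'", "C4'", "C5'", "C2", "C4", "C6", "C8",
          paste0("CX", seq_len(max(0, tpl[["C"]] - 9L))))[seq_len(tpl[["C"]])]
  nn <- c("N1", "N3", "N7", "N9",
          paste0("NX", seq_len(max(0, tpl[["N"]] - 4L))))[seq_len(tpl[["N"]])]
  on <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2", "O6",
          paste0("OX", seq_len(max(0, tpl[["O"]] - 7L))))[seq_len(tpl[["O"]])]
  pn <- c("P", paste0("PX", seq_len(max(0, tpl[["P"]] - 1L))))[
    seq_len(tpl[["P"]])]
  list(names = c(cn, nn, on, pn),
       elements = c(rep("C", tpl[["C"]]), rep("N", tpl[["N"]]),
                    rep("O", tpl[["O"]]), rep("P", tpl[["P"]])))
}

# fixed offsets of the non-C1' template atoms: Fibonacci-sphere directions at
# increasing radii (1.5 to 5 Angstrom), so a nucleotide fills roughly the
# heavy-atom density of real RNA
.template_offsets <- function(m) {
  if (m == 0L) return(matrix(0, 0, 3))
  j <- seq_len(m)
  golden <- pi * (3 - sqrt(5))
  zdir <- 1 - 2 * (j - 0.5) / m
  rad <- sqrt(1 - zdir^2)
  theta <- golden * j
  dir <- cbind(rad * cos(theta), rad * sin(theta), zdir)
  dist <- 1.5 + 3.5 * (j - 1) / max(1, m - 1)
  dir * dist
}

#' Generate one synthetic RNA-like chain
#'
#' Places one C1' atom per nucleotide on the configured helix and surrounds
#' it with the template atoms at fixed offsets plus isotropic Gaussian
#' jitter. Coordinates are a pure function of the seed. B-factors are left
#' at zero; see \code{\link{assignBfactors}}.
#'
#' @param nNucleotides chain length (>= 3).
#' @param config a \linkS4class{GeneratorConfig}.
#' @param chainId chain identifier.
#' @param seed geometry seed (default: the config's root seed).
#' @return data.frame of atoms (the chain's rows of a
#'   \linkS4class{StructureSet}).
#' @export
generateChain <- function(nNucleotides, config, chainId = "A",
                          seed = config@seed) {
  stopifnot(is(config, "GeneratorConfig"))
  if (nNucleotides < 3L) stop("need at least 3 nucleotides")
  tpl <- .template_names(config@template)
  perNt <- length(tpl$names)
  offsets <- rbind(c(0, 0, 0), .template_offsets(perNt - 1L))
  coords <- .with_seed(seed, function() {
    # chain axis: unit-speed walk with random bending, pulled back toward
    # the origin so the tube folds into a compact blob; bendSd = 0 and
    # confinement = 0 reduce it to a straight line (pure helix)
    axis <- matrix(0, nNucleotides, 3)
    dir <- c(0, 0, 1)
    for (i in 2:nNucleotides) {
      prev <- axis[i - 1L, ]
      pull <- if (config@confinement > 0 && sqrt(sum(prev^2)) > 1)
        -config@confinement * prev / sqrt(sum(prev^2)) else c(0, 0, 0)
      dir <- dir + stats::rnorm(3, sd = config@bendSd) + pull
      dir <- dir / sqrt(sum(dir^2))
      axis[i, ] <- prev + config@rise * dir
    }
    # parallel-transported frame; C1' atoms ring the axis at the helix
    # radius, advancing by the twist per nucleotide
    tangents <- rbind(axis[2, ] - axis[1, ],
                      axis[pmin(2:nNucleotides + 0L, nNucleotides), ] -
                        axis[(2:nNucleotides) - 1L, ])
    tangents <- tangents / sqrt(rowSums(tangents^2))
    backbone <- matrix(0, nNucleotides, 3)
    normal <- c(1, 0, 0)
    normal <- normal - sum(normal * tangents[1, ]) * tangents[1, ]
    normal <- normal / sqrt(sum(normal^2))
    for (i in seq_len(nNucleotides)) {
      t_i <- tangents[i, ]
      normal <- normal - sum(normal * t_i) * t_i
      normal <- normal / sqrt(sum(normal^2))
      binorm <- c(t_i[2] * normal[3] - t_i[3] * normal[2],
                  t_i[3] * normal[1] - t_i[1] * normal[3],
                  t_i[1] * normal[2] - t_i[2] * normal[1])
      theta <- (i - 1L) * config@twist * pi / 180
      backbone[i, ] <- axis[i, ] +
        config@radius * (cos(theta) * normal + sin(theta) * binorm)
    }
    out <- matrix(0, nNucleotides * perNt, 3)
    for (i in seq_len(nNucleotides)) {
      jitter <- if (config@jitterSd > 0)
        matrix(stats::rnorm(perNt * 3, sd = config@jitterSd), perNt, 3)
      else matrix(0, perNt, 3)
      jitter[1, ] <- 0  # the C1' sits exactly on the helix
      out[(i - 1L) * perNt + seq_len(perNt), ] <-
        sweep(offsets + jitter, 2, backbone[i, ], "+")
    }
    out
  })
  data.frame(
    chain = chainId,
    resno = rep(seq_len(nNucleotides), each = perNt),
    resid = "A",
    elety = rep(tpl$names, nNucleotides),
    element = rep(tpl$elements, nNucleotides),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    b = 0,
    stringsAsFactors = FALSE)
}

#' Assign ground-truth B-factors from local contact density
#'
#' For every atom, raw B = base - slope * (number of other heavy atoms
#' within the interaction radius) + N(0, noiseSd), floored at 0.01: a
#' weighted-contact-number-style law in which poorly packed atoms (chain
#' termini) are the most flexible. With zero noise the per-chain correlation
#' between B and contact count is exactly -1.
#'
#' @param atoms data.frame of one chain's atoms.
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed noise seed (default: the config's root seed).
#' @return the atom data.frame with \code{b} filled in.
#' @export
assignBfactors <- function(atoms, config, seed = config@seed) {
  stopifnot(is(config, "GeneratorConfig"))
  heavy <- atoms$element %in% HEAVY_ELEMENTS
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  counts <- rowSums(D <= config@interactionRadius) - 1L
  noise <- if (config@noiseSd > 0)
    .with_seed(seed, function() stats::rnorm(sum(heavy),
                                             sd = config@noiseSd))
  else rep(0, sum(heavy))
  b <- config@bfactorBase - config@bfactorSlope * counts + noise
  atoms$b[heavy] <- pmax(b, 0.01)
  atoms
}

#' Generate a full synthetic structure set
#'
#' Draws each chain's length, generates geometry and B-factors with seeds
#' derived from the root seed, writes one PDB file per chain via
#' \code{\link{writeStructure}}, and writes a YAML manifest recording every
#' parameter and derived seed, so the whole set can be regenerated
#' byte-identically.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param dir output directory (created if needed); \code{NULL} skips
#'   writing files.
#' @return list: \code{structures} (list of per-chain
#'   \linkS4class{StructureSet}s), \code{paths}, \code{manifest}.
#' @export
generateStructures <- function(config, dir = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  ids <- c(LETTERS, letters, as.character(0:9))
  if (config@nChains > length(ids)) stop("too many chains for PDB ids")
  ids <- ids[seq_len(config@nChains)]
  choices <- seq(config@nucleotides[1], config@nucleotides[2])
  lengths <- .with_seed(config@seed, function()
    choices[sample.int(length(choices), config@nChains, replace = TRUE)])
  structures <- vector("list", config@nChains)
  paths <- character(config@nChains)
  for (i in seq_len(config@nChains)) {
    gseed <- config@seed + 101L * i
    bseed <- config@seed + 101L * i + 50L
    atoms <- generateChain(lengths[i], config, chainId = ids[i],
                           seed = gseed)
    atoms <- assignBfactors(atoms, config, seed = bseed)
    ss <- StructureSet(atoms, source = paste0("synthetic:", ids[i]))
    structures[[i]] <- ss
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths[i] <- file.path(dir, paste0("chain_", ids[i], ".pdb"))
      writeStructure(ss, paths[i])
    }
  }
  manifest <- list(
    generator = list(
      n_chains = config@nChains,
      nucleotides = as.list(config@nucleotides),
      rise = config@rise, radius = config@radius, twist = config@twist,
      bend_sd = config@bendSd, confinement = config@confinement,
      template = as.list(config@template), jitter_sd = config@jitterSd,
      bfactor = list(base = config@bfactorBase,
                     slope = config@bfactorSlope,
                     interaction_radius = config@interactionRadius,
                     noise_sd = config@noiseSd),
      seed = config@seed),
    chains = lapply(seq_len(config@nChains), function(i)
      list(id = ids[i], n_nucleotides = lengths[i],
           geometry_seed = config@seed + 101L * i,
           bfactor_seed = config@seed + 101L * i + 50L)))
  if (!is.null(dir))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  list(structures = structures,
       paths = if (is.null(dir)) character(0) else paths,
       manifest = manifest)
}
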