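#' @title Synthetic proximity-methylation data with known ground truth
#'
#' @description
#' Generates everything the downstream stages consume: a genome with NDR
#' annotation, a viewpoint, a sparse set of planted long-range contacts,
#' NPC-style feature flags, latent multi-viewpoint compartments, NB count
#' emission for targeted and control strains, fragment emission for the
#' counting stage, and bisulfite trace profiles. Every routine is
#' deterministic given (config, seed).
#'
#' @name simulator
NULL

#' Simulator configuration
#'
#' Defaults describe a yeast-like study: NDRs every ~2.5 kb of ~150 bp
#' width, a mean control depth of 50 fragments per NDR, NB dispersion 0.05
#' with 2 replicates per group, local enrichment decaying exponentially
#' with a 400 bp half-distance, planted long-range contacts at fold 4, and
#' an NPC-like feature marking 11.3% of NDRs with 6-fold enrichment among
#' contacts.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param ndr_spacing mean start-to-start NDR spacing (bp).
#' @param ndr_width NDR width (bp).
#' @param depth mean control count per NDR.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`); 0
#'   gives Poisson emission.
#' @param n_reps replicates per group.
#' @param f_local local enrichment amplitude at the viewpoint (excess fold
#'   at distance 0); 0 disables local enrichment.
#' @param h_local local half-distance (bp).
#' @param f_contact fold change at planted contacts.
#' @param n_contacts number of planted long-range contacts.
#' @param npc_fraction background fraction of NPC-flagged NDRs.
#' @param npc_enrichment fold enrichment of the NPC flag among contacts.
#' @param n_compartments latent compartments (multi-viewpoint runs).
#' @param n_vps number of viewpoints (multi-viewpoint runs).
#' @param halo when TRUE, NDRs neighboring a planted contact receive an
#'   exponentially decaying share of the contact enrichment (half-distance
#'   `h_local`), emulating the decay of signal around true contact centers.
#' @param accessibility_sdlog lognormal sd of per-NDR accessibility
#'   weights.
#' @param depth_sdlog lognormal sd of per-sample depth factors.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_chrom = 5, chrom_length = 1e6, ndr_spacing = 2500,
                       ndr_width = 150, depth = 50, dispersion = 0.05,
                       n_reps = 2, f_local = 8, h_local = 400,
                       f_contact = 4, n_contacts = 50,
                       npc_fraction = 0.113, npc_enrichment = 6,
                       n_compartments = 3, n_vps = 8, halo = FALSE,
                       accessibility_sdlog = 0.5, depth_sdlog = 0.1) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
    ndr_spacing = ndr_spacing, ndr_width = ndr_width, depth = depth,
    dispersion = dispersion, n_reps = n_reps, f_local = f_local,
    h_local = h_local, f_contact = f_contact, n_contacts = n_contacts,
    npc_fraction = npc_fraction, npc_enrichment = npc_enrichment,
    n_compartments = n_compartments, n_vps = n_vps, halo = halo,
    accessibility_sdlog = accessibility_sdlog, depth_sdlog = depth_sdlog)
  pos <- c("n_chrom", "chrom_length", "ndr_spacing", "ndr_width", "depth",
    "n_reps", "h_local", "f_contact", "n_compartments", "n_vps")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) stop(p, " must be positive")
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$f_local < 0) stop("f_local must be >= 0")
  if (cfg$ndr_spacing <= cfg$ndr_width) {
    stop("ndr_spacing must exceed ndr_width")
  }
  if (cfg$npc_fraction <= 0 || cfg$npc_fraction >= 1) {
    stop("npc_fraction must lie in (0, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome and its NDR annotation
#'
#' NDR start-to-start gaps are drawn as width plus an exponential with the
#' configured mean spacing; widths are fixed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `chrom_sizes` (named vector) and `ndrs`
#'   ([ndr_annotation()]).
#' @export
simulate_genome <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(config$n_chrom)) {
    chrom <- sprintf("chr%02d", ci)
    gap_mean <- config$ndr_spacing - config$ndr_width
    pos <- floor(stats::rexp(1, 1 / gap_mean))
    starts <- numeric(0)
    while (pos + config$ndr_width <= config$chrom_length) {
      starts <- c(starts, pos)
      pos <- pos + config$ndr_width +
        floor(stats::rexp(1, 1 / gap_mean)) + 1
    }
    rows[[ci]] <- data.frame(chrom = chrom, start = starts,
      end = starts + config$ndr_width, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$ndr_id <- sprintf("ndr_%05d", seq_len(nrow(df)))
  sizes <- rep(config$chrom_length, config$n_chrom)
  names(sizes) <- sprintf("chr%02d", seq_len(config$n_chrom))
  list(chrom_sizes = sizes, ndrs = ndr_annotation(df, sizes))
}

# Internal: sample NPC flags with enrichment among contacts.
.plant_npc <- function(n, contact_idx, config) {
  p_bg <- config$npc_fraction
  p_fg <- min(0.95, config$npc_enrichment * p_bg)
  flags <- stats::runif(n) < p_bg
  flags[contact_idx] <- stats::runif(length(contact_idx)) < p_fg
  flags
}

#' Plant ground truth: viewpoint, contacts, flags, compartments
#'
#' The viewpoint insertion (1 kb, emulating an operator array) is placed at
#' the center of chromosome 1. Contacts are sampled uniformly from NDRs
#' eligible for long-range calling (midpoint > 30 kb from the viewpoint or
#' on another chromosome), preferentially NPC-flagged at the configured
#' enrichment, and assigned balanced latent compartment labels.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `"sim_truth"`: `chrom_sizes`, `ndrs`, `vp`,
#'   `contacts` (data.frame `ndr_id`, `fold`, `compartment`), `npc_flags`
#'   (named logical), `config`.
#' @export
plant_truth <- function(genome, config, seed = 1) {
  set.seed(seed + 1L)
  ndrs <- genome$ndrs
  mid_vp <- floor(config$chrom_length / 2)
  vp <- viewpoint("vp1", names(genome$chrom_sizes)[1L],
    mid_vp - 500, mid_vp + 500, genome$chrom_sizes)
  d_vp <- ifelse(ndrs$chrom == vp$chrom,
    abs(.mid(ndrs$start, ndrs$end) - .mid(vp$start, vp$end)), Inf)
  eligible <- which(ndrs$chrom != vp$chrom | d_vp > 30000)
  if (length(eligible) < config$n_contacts) {
    stop("not enough NDRs eligible for ", config$n_contacts, " contacts")
  }
  contact_idx <- sort(sample(eligible, config$n_contacts))
  npc <- .plant_npc(nrow(ndrs), contact_idx, config)
  names(npc) <- ndrs$ndr_id
  comp <- sample(rep_len(seq_len(config$n_compartments),
    length(contact_idx)))
  contacts <- data.frame(ndr_id = ndrs$ndr_id[contact_idx],
    fold = rep(config$f_contact, length(contact_idx)),
    compartment = comp, stringsAsFactors = FALSE)
  structure(list(chrom_sizes = genome$chrom_sizes, ndrs = ndrs, vp = vp,
    contacts = contacts, npc_flags = npc, config = config),
    class = "sim_truth")
}

# Internal: per-NDR targeted/control enrichment for one viewpoint.
# E = 1 + f_local * 2^(-d/h) on the viewpoint chromosome, f_contact at
# contacts, optional exponentially decaying halo around contact centers.
.enrichment_profile <- function(ndrs, vp, contact_ids, config,
                                fold = config$f_contact) {
  mid <- .mid(ndrs$start, ndrs$end)
  e <- rep(1, nrow(ndrs))
  cis <- ndrs$chrom == vp$chrom
  if (config$f_local > 0 && any(cis)) {
    d <- abs(mid[cis] - .mid(vp$start, vp$end))
    e[cis] <- 1 + config$f_local * 2^(-d / config$h_local)
  }
  ci <- match(contact_ids, ndrs$ndr_id)
  if (config$halo && length(ci) > 0L) {
    for (k in ci) {
      near <- which(ndrs$chrom == ndrs$chrom[k])
      d <- abs(mid[near] - mid[k])
      halo <- 1 + (fold - 1) * 2^(-d / config$h_local)
      e[near] <- pmax(e[near], halo)
    }
  }
  e[ci] <- fold
  e
}

# Internal: NB or Poisson emission.
.emit <- function(mu, alpha) {
  if (alpha <= 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
}

#' Simulate targeted and control counts for one viewpoint
#'
#' Control expectation is `depth * accessibility`, with per-NDR lognormal
#' accessibility weights (mean 1) and per-sample lognormal depth factors;
#' the targeted expectation multiplies in the enrichment profile (local
#' decay around the viewpoint, planted fold at contacts, 1 elsewhere).
#' Counts are NB with the configured dispersion, independent across
#' replicates.
#'
#' @param truth a [plant_truth()] result.
#' @param config a [sim_config()] (defaults to the one inside `truth`).
#' @param seed integer seed.
#' @return list of class `"sim_dataset"`: `counts` ([mtac_counts()]),
#'   `truth`, `enrichment` (per-NDR expected fold), `seed`.
#' @export
simulate_counts <- function(truth, config = truth$config, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed + 2L)
  ndrs <- truth$ndrs
  n <- nrow(ndrs)
  acc <- stats::rlnorm(n, meanlog = -config$accessibility_sdlog^2 / 2,
    sdlog = config$accessibility_sdlog)
  e <- .enrichment_profile(ndrs, truth$vp, truth$contacts$ndr_id, config)
  n_s <- 2L * config$n_reps
  depth_f <- stats::rlnorm(n_s, meanlog = -config$depth_sdlog^2 / 2,
    sdlog = config$depth_sdlog)
  group <- rep(c("targeted", "control"), each = config$n_reps)
  counts <- matrix(0L, nrow = n, ncol = n_s,
    dimnames = list(ndrs$ndr_id,
      paste0(group, "_", rep(seq_len(config$n_reps), 2L))))
  for (j in seq_len(n_s)) {
    mu <- config$depth * depth_f[j] * acc *
      (if (group[j] == "targeted") e else 1)
    counts[, j] <- .emit(mu, config$dispersion)
  }
  structure(list(
    counts = mtac_counts(counts, group = group),
    truth = truth, enrichment = e, seed = seed
  ), class = "sim_dataset")
}

#' One-call single-viewpoint simulation
#'
#' Convenience wrapper: genome, truth, counts, all under one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `sim_dataset`, see [simulate_counts()].
#' @export
simulate_mtac <- function(config = sim_config(), seed = 1) {
  genome <- simulate_genome(config, seed)
  truth <- plant_truth(genome, config, seed)
  simulate_counts(truth, config, seed)
}

#' Multi-viewpoint simulation with latent compartments
#'
#' One shared genome and one shared set of contact NDRs with balanced
#' latent compartment labels. Each viewpoint is assigned a compartment
#' (round-robin) and placed on a distinct chromosome position; a contact
#' NDR is enriched (fold `f_contact`) only for viewpoints of its own
#' compartment, which induces positively correlated signals within
#' compartments and uncorrelated/negative signals across, the structure
#' correlation clustering assumes. Contacts are sampled at least 30 kb
#' from every viewpoint (or trans to it) so every planted contact is a
#' long-range interaction for every viewpoint.
#'
#' @param config a [sim_config()]; `n_vps >= 2`, `n_compartments >= 1`.
#' @param seed integer seed.
#' @return list of class `"sim_multivp"`: `datasets` (named list of
#'   `sim_dataset`, one per viewpoint), `vps` (list of [viewpoint()]s),
#'   `vp_compartment` (named integer), `contacts` (shared truth table),
#'   `genome`, `npc_flags`, `config`, `seed`.
#' @export
simulate_multivp <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_vps < 2L) stop("multi-viewpoint simulation needs n_vps >= 2")
  genome <- simulate_genome(config, seed)
  set.seed(seed + 10L)
  ndrs <- genome$ndrs
  chroms <- names(genome$chrom_sizes)
  # spread viewpoints over chromosomes and positions
  vp_chrom <- chroms[(seq_len(config$n_vps) - 1L) %% length(chroms) + 1L]
  frac <- 0.25 + 0.5 * (seq_len(config$n_vps) - 1L) / max(config$n_vps - 1L, 1L)
  vps <- lapply(seq_len(config$n_vps), function(v) {
    center <- floor(config$chrom_length * frac[v])
    viewpoint(paste0("vp", v), vp_chrom[v], center - 500, center + 500,
      genome$chrom_sizes)
  })
  names(vps) <- vapply(vps, `[[`, "", "name")
  vp_comp <- rep_len(seq_len(config$n_compartments), config$n_vps)
  names(vp_comp) <- names(vps)
  mid <- .mid(ndrs$start, ndrs$end)
  far_from_all <- rep(TRUE, nrow(ndrs))
  for (vp in vps) {
    d <- ifelse(ndrs$chrom == vp$chrom,
      abs(mid - .mid(vp$start, vp$end)), Inf)
    far_from_all <- far_from_all & (d > 30000)
  }
  eligible <- which(far_from_all)
  if (length(eligible) < config$n_contacts) {
    stop("not enough NDRs far from every viewpoint")
  }
  contact_idx <- sort(sample(eligible, config$n_contacts))
  comp <- sample(rep_len(seq_len(config$n_compartments),
    length(contact_idx)))
  contacts <- data.frame(ndr_id = ndrs$ndr_id[contact_idx],
    fold = config$f_contact, compartment = comp, stringsAsFactors = FALSE)
  npc <- .plant_npc(nrow(ndrs), contact_idx, config)
  names(npc) <- ndrs$ndr_id
  datasets <- vector("list", config$n_vps)
  names(datasets) <- names(vps)
  for (v in seq_len(config$n_vps)) {
    own <- contacts$ndr_id[contacts$compartment == vp_comp[v]]
    truth <- structure(list(chrom_sizes = genome$chrom_sizes, ndrs = ndrs,
      vp = vps[[v]],
      contacts = contacts[contacts$compartment == vp_comp[v], , drop = FALSE],
      npc_flags = npc, config = config), class = "sim_truth")
    datasets[[v]] <- simulate_counts(truth, config, seed = seed + 100L + v)
  }
  structure(list(datasets = datasets, vps = vps, vp_compartment = vp_comp,
    contacts = contacts, genome = genome, npc_flags = npc, config = config,
    seed = seed), class = "sim_multivp")
}

#' Emit fragments realizing a simulated count matrix
#'
#' Deterministically lays `counts[i, j]` fragments fully inside NDR `i`
#' for sample `j` (so multi-overlap counting recovers the matrix exactly
#' when NDRs do not overlap), plus `n_background` fragments per sample in
#' inter-NDR gaps that contribute to library size only.
#'
#' @param dataset a `sim_dataset` from [simulate_counts()].
#' @param n_background background fragments per sample.
#' @param fragment_width fragment width (bp), clipped to the NDR width.
#' @return data.frame with columns `chrom`, `start`, `end`, `sample`.
#' @export
simulate_fragments <- function(dataset, n_background = 0,
                               fragment_width = 120) {
  stopifnot(inherits(dataset, "sim_dataset"))
  ndrs <- dataset$truth$ndrs
  counts <- dataset$counts$counts
  w <- min(fragment_width, min(ndrs$end - ndrs$start))
  out <- list()
  for (j in seq_len(ncol(counts))) {
    reps <- counts[, j]
    idx <- rep.int(seq_len(nrow(ndrs)), reps)
    if (length(idx) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ndrs$chrom[idx], start = ndrs$start[idx],
        end = ndrs$start[idx] + w, sample = colnames(counts)[j],
        stringsAsFactors = FALSE)
    }
    if (n_background > 0L) {
      # place background fragments beyond the last NDR of chromosome 1
      chrom1 <- names(dataset$truth$chrom_sizes)[1L]
      base <- max(ndrs$end[ndrs$chrom == chrom1]) + 1000
      starts <- base + (seq_len(n_background) - 1L) * 10
      out[[length(out) + 1L]] <- data.frame(chrom = chrom1, start = starts,
        end = starts + 5, sample = colnames(counts)[j],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate noisy exponential-decay observations
#'
#' Points from `signal = A * 2^(-d/h)` with multiplicative lognormal noise,
#' the generative model behind the distance-decay fits.
#'
#' @param n number of points.
#' @param amplitude signal at distance 0.
#' @param half_distance decay half-distance (bp).
#' @param sigma lognormal noise sd (0 = noiseless).
#' @param d_max maximal distance (bp); distances are uniform on `[0, d_max]`.
#' @param seed integer seed.
#' @return data.frame with columns `distance`, `signal`.
#' @export
simulate_decay_points <- function(n = 200, amplitude = 4,
                                  half_distance = 400, sigma = 0.2,
                                  d_max = 2000, seed = 1) {
  set.seed(seed)
  d <- stats::runif(n, 0, d_max)
  s <- amplitude * 2^(-d / half_distance)
  if (sigma > 0) {
    s <- s * stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  data.frame(distance = d, signal = s)
}

#' Simulate a Sanger trace profile from planted methylation rates
#'
#' At each GC-site C of the reference, channel intensities are
#' `I_C = rate` and `I_T = 1 - rate` (times a common scale), with optional
#' multiplicative lognormal noise; all other positions get a clean
#' intensity on the reference base channel.
#'
#' @param rates methylation rates in `[0, 1]`, one per GC site of
#'   `reference` (in order).
#' @param reference unconverted reference sequence (character scalar).
#' @param sigma lognormal noise sd.
#' @param seed integer seed.
#' @param scale common intensity scale.
#' @return a trace profile data.frame: `position` (1-based), `ref_base`,
#'   `I_A`, `I_C`, `I_G`, `I_T`.
#' @export
simulate_trace <- function(rates, reference, sigma = 0, seed = 1,
                           scale = 1000) {
  set.seed(seed)
  bases <- strsplit(toupper(reference), "")[[1L]]
  sites <- gc_sites(reference)
  if (length(rates) != length(sites)) {
    stop("need one rate per GC site (", length(sites), " sites, ",
      length(rates), " rates)")
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- length(bases)
  prof <- data.frame(position = seq_len(n), ref_base = bases,
    I_A = 0, I_C = 0, I_G = 0, I_T = 0, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    col <- paste0("I_", bases[i])
    if (col %in% names(prof)) prof[i, col] <- scale
  }
  noise <- function(k) {
    if (sigma > 0) {
      stats::rlnorm(k, meanlog = -sigma^2 / 2, sdlog = sigma)
    } else {
      rep(1, k)
    }
  }
  prof$I_C[sites] <- scale * rates * noise(length(sites))
  prof$I_T[sites] <- scale * (1 - rates) * noise(length(sites))
  prof
}

#' Write a simulated dataset as pipeline input files
#'
#' Writes the NDR BED, chromosome sizes, counts TSV, design TSV and truth
#' TSV under a directory, the file set the pipeline entry point consumes.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ndrs = file.path(dir, "ndrs.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv"),
    vp = file.path(dir, "viewpoint.tsv")
  )
  write_bed(dataset$truth$ndrs, paths[["ndrs"]])
  write_chrom_sizes(dataset$truth$chrom_sizes, paths[["chrom_sizes"]])
  write_counts(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$counts$samples, paths[["design"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$contacts, paths[["truth"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  vp <- dataset$truth$vp
  utils::write.table(
    data.frame(name = vp$name, chrom = vp$chrom, start = vp$start,
      end = vp$end, stringsAsFactors = FALSE),
    paths[["vp"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
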