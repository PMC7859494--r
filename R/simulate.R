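# Synthetic HTQS experiments with known ground truth.
#
# The generator emulates a zonal surface-transect study: a lognormal mock
# community with known copies per liter, nine spike-in standards at four
# decade-spaced concentrations, multinomial sequencing with per-taxon
# efficiency noise, distance-decay spatial structure, and environmental
# gradients confined to configured ranges.

#' Simulation configuration
#'
#' Defaults describe the stated world the generator emulates: 20 stations,
#' ~1200 OTUs, lognormal abundances rescaled so per-sample totals fall in
#' 1.86e8--1.14e9 copies per liter, nine spike-ins (3 at 1e3, 2 each at
#' 1e4/1e5/1e6 copies), environmental variables inside the survey's reported
#' ranges, sequenced-template recovery ratios of 3e-4--1.5e-3 (so the spike
#' panel is sequenceable next to ~1e9 biological copies) and filtered
#' volumes in 4.25--7.3 L.
#'
#' @param n_samples number of stations.
#' @param n_otus number of biological OTUs (includes the injected
#'   archaea/chloroplast/unassigned fractions).
#' @param lognormal_mu,lognormal_sigma parameters of the per-OTU base
#'   log-abundance (natural log).
#' @param total_copies_range per-sample community total (copies per liter)
#'   drawn uniformly from this range.
#' @param spikein_copies copy numbers of the spike-in panel.
#' @param depth reads per sample (multinomial library size).
#' @param noise_cv coefficient of variation of the per-taxon lognormal
#'   amplification efficiency (0 = perfectly proportional sequencing).
#'   Unknown for real spike-in panels; a free simulation knob.
#' @param spatial_decay strength of the spatial component of community
#'   structure: 0 gives i.i.d. compositional noise (no distance decay),
#'   larger values make composition track smooth spatial gradients so
#'   similarity decays with great-circle distance.
#' @param env_ranges named list of `c(min, max)` ranges for the
#'   environmental variables.
#' @param frac_archaea,frac_chloroplast,frac_unassigned fractions of OTUs
#'   labeled as non-bacterial / unassigned (cleaning-test material).
#' @param seed integer RNG seed; fixes every emitted value.
#' @return classed list of settings.
#' @export
sim_config <- function(n_samples = 20L, n_otus = 1200L,
                       lognormal_mu = 0, lognormal_sigma = 2,
                       total_copies_range = c(1.86e8, 1.14e9),
                       spikein_copies = c(rep(1e3, 3), rep(1e4, 2),
                                          rep(1e5, 2), rep(1e6, 2)),
                       depth = 1e5, noise_cv = 0.2, spatial_decay = 1.5,
                       env_ranges = list(
                         temperature = c(28.55, 29.68),
                         salinity = c(33.66, 35.12),
                         nox = c(0.014, 0.104),
                         drp = c(0.01, 0.15),
                         silicate = c(0.57, 1.93),
                         chla = c(5.4, 48.8),
                         bacterial_abundance = c(1.15e5, 1.68e5)),
                       frac_archaea = 0.02, frac_chloroplast = 0.015,
                       frac_unassigned = 0.01, seed = 1L) {
  if (n_samples < 1 || n_otus < 1)
    stop("n_samples and n_otus must be positive", call. = FALSE)
  stopifnot(lognormal_sigma > 0, all(total_copies_range > 0),
            all(spikein_copies > 0),
            length(unique(spikein_copies)) >= 2,
            noise_cv >= 0, spatial_decay >= 0,
            frac_archaea >= 0, frac_chloroplast >= 0, frac_unassigned >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_otus = as.integer(n_otus),
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 total_copies_range = total_copies_range,
                 spikein_copies = spikein_copies,
                 depth = depth, noise_cv = noise_cv,
                 spatial_decay = spatial_decay,
                 env_ranges = env_ranges,
                 frac_archaea = frac_archaea,
                 frac_chloroplast = frac_chloroplast,
                 frac_unassigned = frac_unassigned,
                 seed = as.integer(seed)),
            class = "htqs_sim_config")
}

# smooth bounded field along the normalized transect position s in [0,1]:
# a random linear gradient plus one sine wave, squashed into (lo, hi)
.bounded_gradient <- function(s, lo, hi, noise_sd = 0.4) {
  z <- stats::rnorm(1, 0, 2) * (s - 0.5) +
    stats::rnorm(1, 0, 1) * sin(2 * pi * (s + stats::runif(1))) +
    stats::rnorm(length(s), 0, noise_sd)
  lo + (hi - lo) * stats::plogis(z)
}

#' Generate a true community and station metadata on a zonal transect
#'
#' Stations are placed on a single west-to-east transect that crosses the
#' antimeridian (monotone longitudes), mirroring a trans-basin cruise.
#' Each OTU's log abundance is a base lognormal draw plus a spatial field:
#' i.i.d. noise plus `spatial_decay` times a smooth random function of
#' transect position, so community similarity decays with great-circle
#' distance when `spatial_decay > 0`.  Per-sample totals are rescaled to a
#' uniform draw from `total_copies_range`.
#'
#' @param config a [sim_config()].
#' @return list with `true_abundance` (samples x OTUs matrix, copies per
#'   liter), `efficiency` (per-OTU amplification factors, mean 1),
#'   `spikein_efficiency`, and `metadata` (a [sample_metadata()] frame).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "htqs_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_otus

  sample_ids <- sprintf("S%02d", seq_len(n))
  otu_ids <- sprintf("OTU%04d", seq_len(p))

  # transect from 158.77 E eastwards across 180 to 126.21 W, heading south
  lon_raw <- seq(158.77, 360 - 126.21, length.out = max(n, 2))[seq_len(n)]
  lon <- ifelse(lon_raw > 180, lon_raw - 360, lon_raw)
  lat <- seq(28.96, 9.31, length.out = max(n, 2))[seq_len(n)] +
    stats::rnorm(n, 0, 0.3)
  lat <- pmin(pmax(lat, -90), 90)

  # cumulative along-track distance, normalized to [0,1]
  s <- rep(0, n)
  if (n > 1) {
    seg <- vapply(seq_len(n - 1), function(i) {
      .haversine_km(lon[i], lat[i], lon[i + 1], lat[i + 1])
    }, numeric(1))
    s <- c(0, cumsum(seg))
    s <- s / max(s)
  }

  mu <- stats::rnorm(p, config$lognormal_mu, config$lognormal_sigma)
  a <- stats::rnorm(p)        # per-OTU linear trend along the transect
  b <- stats::rnorm(p)        # per-OTU sine component
  phi <- stats::runif(p)
  eps <- matrix(stats::rnorm(n * p, 0, 1), n, p)
  spatial <- outer(s, a) + sin(2 * pi * outer(s, rep(1, p)) +
                                 2 * pi * matrix(phi, n, p, byrow = TRUE)) *
    matrix(b, n, p, byrow = TRUE)
  logab <- matrix(mu, n, p, byrow = TRUE) + eps +
    config$spatial_decay * spatial
  ab <- exp(logab)
  totals <- stats::runif(n, config$total_copies_range[1],
                         config$total_copies_range[2])
  ab <- ab / rowSums(ab) * totals
  dimnames(ab) <- list(sample_ids, otu_ids)

  cv <- config$noise_cv
  sd_log <- sqrt(log(1 + cv^2))
  efficiency <- stats::rlnorm(p, -sd_log^2 / 2, sd_log)
  names(efficiency) <- otu_ids
  k <- length(config$spikein_copies)
  spikein_efficiency <- stats::rlnorm(k, -sd_log^2 / 2, sd_log)

  er <- config$env_ranges
  md <- data.frame(
    sample_id = sample_ids,
    temperature = .bounded_gradient(s, er$temperature[1], er$temperature[2]),
    salinity = .bounded_gradient(s, er$salinity[1], er$salinity[2]),
    nox = .bounded_gradient(s, er$nox[1], er$nox[2]),
    drp = .bounded_gradient(s, er$drp[1], er$drp[2]),
    silicate = .bounded_gradient(s, er$silicate[1], er$silicate[2]),
    chla = .bounded_gradient(s, er$chla[1], er$chla[2]),
    bacterial_abundance = .bounded_gradient(s, er$bacterial_abundance[1],
                                            er$bacterial_abundance[2]),
    longitude = lon, latitude = lat,
    # sequenced template fraction of the extract; small (ng of template
    # from a ug-scale extract) so the 1e3-1e6 spike panel is sequenceable
    # next to ~1e9 biological copies
    recovery_ratio = stats::runif(n, 3e-4, 1.5e-3),
    volume = stats::runif(n, 4.25, 7.3),
    stringsAsFactors = FALSE)

  list(true_abundance = ab, efficiency = efficiency,
       spikein_efficiency = spikein_efficiency,
       metadata = sample_metadata(md), transect_position = s)
}

#' Simulate amplicon sequencing of a true community with spike-ins
#'
#' For each sample, the sequenceable pool is the spike-in panel at its
#' added copy numbers plus each OTU at `true_abundance * V * R` copies
#' (the copies actually present in the sequenced DNA aliquot).  Pool
#' weights are multiplied by per-taxon amplification efficiencies and read
#' counts drawn multinomially at the configured depth, so column sums equal
#' depth exactly and taxa compete for reads.  A small archaea, chloroplast,
#' and unassigned fraction is labeled for cleaning tests.
#'
#' @param community output of [generate_community()].
#' @param metadata sample metadata supplying `recovery_ratio` and `volume`.
#' @param config the [sim_config()].
#' @param sampling `"multinomial"` (default: reads compete for the fixed
#'   depth) or `"expected"` (deterministic expected reads apportioned to
#'   the depth by largest remainder -- the noiseless limit used for
#'   calibration-recovery checks).
#' @return list with `counts` (a [count_table()] including spike-in
#'   columns), `taxonomy`, and `design` (a [spikein_design()]).
#' @export
simulate_sequencing <- function(community, metadata, config,
                                sampling = c("multinomial", "expected")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(config, "htqs_sim_config"))
  if (config$depth <= 0) stop("depth must be positive", call. = FALSE)
  set.seed(config$seed + 1000L)
  ab <- community$true_abundance
  n <- nrow(ab); p <- ncol(ab)
  stopifnot(identical(rownames(ab), metadata$sample_id))

  spike_ids <- sprintf("SPIKE%d", seq_along(config$spikein_copies))
  design <- spikein_design(spike_ids, config$spikein_copies)

  eff_b <- community$efficiency
  eff_s <- community$spikein_efficiency
  counts <- matrix(0L, n, p + length(spike_ids),
                   dimnames = list(rownames(ab), c(spike_ids, colnames(ab))))
  for (i in seq_len(n)) {
    pool <- c(design$added_copies * eff_s,
              ab[i, ] * metadata$volume[i] * metadata$recovery_ratio[i] *
                eff_b)
    if (sampling == "multinomial") {
      counts[i, ] <- as.integer(stats::rmultinom(1, size = config$depth,
                                                 prob = pool / sum(pool)))
    } else {
      e <- config$depth * pool / sum(pool)
      fl <- floor(e)
      short <- as.integer(round(config$depth - sum(fl)))
      extra <- integer(length(e))
      if (short > 0)
        extra[order(e - fl, decreasing = TRUE)[seq_len(short)]] <- 1L
      counts[i, ] <- as.integer(fl) + extra
    }
  }

  # taxonomy: synthetic lineages over ~12 phyla with skewed frequencies
  n_arch <- round(config$frac_archaea * p)
  n_chl <- round(config$frac_chloroplast * p)
  n_un <- round(config$frac_unassigned * p)
  category <- rep("bacteria", p)
  special <- sample.int(p, min(p, n_arch + n_chl + n_un))
  category[special[seq_len(min(n_arch, length(special)))]] <- "archaea"
  if (length(special) > n_arch)
    category[special[n_arch + seq_len(min(n_chl, length(special) - n_arch))]] <-
      "chloroplast"
  if (length(special) > n_arch + n_chl)
    category[special[(n_arch + n_chl + 1):length(special)]] <- "unassigned"

  n_phyla <- 12L
  phy_w <- exp(-0.45 * seq_len(n_phyla))
  phylum <- sample.int(n_phyla, p, replace = TRUE, prob = phy_w)
  ord <- sample.int(3, p, replace = TRUE)
  lineage <- ifelse(
    category == "archaea",
    "Archaea;ArchPhylum;ArchClass;ArchOrder",
    ifelse(category == "chloroplast",
           "Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast",
           ifelse(category == "unassigned", "Unassigned",
                  sprintf("Bacteria;Phylum_%02d;Class_%02d;Order_%02d_%d",
                          phylum, phylum, phylum, ord))))
  taxonomy <- taxonomy_table(
    c(spike_ids, colnames(ab)),
    c(rep("Synthetic;SpikeIn", length(spike_ids)), lineage),
    c(rep("spike_in", length(spike_ids)), category))

  list(counts = count_table(counts), taxonomy = taxonomy, design = design)
}

#' Generate a random rooted coalescent tree over OTU identifiers
#'
#' @param otu_ids tip labels (>= 2).
#' @param seed integer seed; the same seed yields the identical newick
#'   string.
#' @return rooted `phylo` with positive branch lengths.
#' @export
generate_tree <- function(otu_ids, seed = 1L) {
  if (length(otu_ids) < 2L)
    stop("need at least 2 OTUs for a tree", call. = FALSE)
  set.seed(seed)
  tr <- ape::rcoal(length(otu_ids), tip.label = otu_ids)
  tr$edge.length <- pmax(tr$edge.length, 1e-9)
  tr
}

#' Run the full generator: community, metadata, sequencing, tree
#'
#' @param config a [sim_config()].
#' @param sampling sequencing mode, see [simulate_sequencing()].
#' @return list with `truth` (true copies per liter), `efficiency`,
#'   `metadata`, `counts`, `taxonomy`, `design`, `tree`.
#' @export
simulate_experiment <- function(config, sampling = "multinomial") {
  comm <- generate_community(config)
  seqd <- simulate_sequencing(comm, comm$metadata, config, sampling)
  tree <- generate_tree(colnames(comm$true_abundance),
                        seed = config$seed + 2000L)
  list(truth = comm$true_abundance, efficiency = comm$efficiency,
       metadata = comm$metadata, counts = seqd$counts,
       taxonomy = seqd$taxonomy, design = seqd$design, tree = tree,
       transect_position = comm$transect_position)
}
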