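# Spike-in calibration and absolute quantification.
#
# Per sample, a standard curve y = a x + b is fit by ordinary least
# squares with y = log10(spike-in reads) and x = log10(added copies).
# The curve is inverted to convert biological read counts to copies in
# the sequenced aliquot (Y_otu), which are scaled to copies per liter of
# seawater by AB_otu = Y_otu / (R * V): dividing by the recovery ratio R
# scales the sequenced aliquot up to the whole DNA extract, dividing by
# the filtered volume V converts to a concentration.

#' Partition a count table into spike-in and biological columns
#'
#' @param counts a [count_table()] that still contains spike-in OTUs.
#' @param taxonomy a [taxonomy_table()] covering the table's OTUs.
#' @param design optional [spikein_design()]; spike-ins listed there but
#'   absent from the table are warned about and recorded as zero reads.
#' @return list with `spikein` and `biological` count tables (either may
#'   have zero columns, returned as a plain matrix in that case).
#' @export
split_spikeins <- function(counts, taxonomy, design = NULL) {
  cat_of <- stats::setNames(taxonomy$category, taxonomy$otu_id)
  unknown <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(unknown) > 0L)
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  is_spike <- cat_of[colnames(counts)] == "spike_in"
  spike <- unclass(counts)[, is_spike, drop = FALSE]
  bio <- unclass(counts)[, !is_spike, drop = FALSE]
  if (!any(is_spike))
    warning("no spike-in OTUs found in the count table", call. = FALSE)
  if (!is.null(design)) {
    missing_sp <- setdiff(design$spikein_id, colnames(spike))
    if (length(missing_sp) > 0L) {
      warning("spike-ins in design but absent from table (recorded as 0 reads): ",
              paste(missing_sp, collapse = ", "), call. = FALSE)
      zeros <- matrix(0L, nrow(counts), length(missing_sp),
                      dimnames = list(rownames(counts), missing_sp))
      spike <- cbind(spike, zeros)
    }
  }
  list(spikein = if (ncol(spike) > 0) count_table(spike) else spike,
       biological = if (ncol(bio) > 0) count_table(bio) else bio)
}

#' Remove non-bacterial OTUs and global singletons
#'
#' Drops OTUs categorized as `spike_in`, `archaea`, or `chloroplast` and
#' OTUs whose total read count across all samples is exactly 1 (the
#' upstream clustering convention for singletons).  `unassigned` OTUs are
#' retained.
#'
#' @param counts a [count_table()].
#' @param taxonomy a [taxonomy_table()] covering all OTUs.
#' @return cleaned [count_table()].
#' @export
clean_biological <- function(counts, taxonomy) {
  cat_of <- stats::setNames(taxonomy$category, taxonomy$otu_id)
  unknown <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(unknown) > 0L)
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  keep_cat <- !(cat_of[colnames(counts)] %in%
                  c("spike_in", "archaea", "chloroplast"))
  totals <- colSums(unclass(counts))
  keep <- keep_cat & totals != 1
  if (!any(keep))
    stop("no bacterial OTUs remain after cleaning", call. = FALSE)
  count_table(unclass(counts)[, keep, drop = FALSE])
}

#' Fit per-sample spike-in standard curves
#'
#' Ordinary least squares of `y = log10(reads)` on `x = log10(added
#' copies)` for each sample.  Spike-ins with zero reads are excluded from
#' the fit and reported; samples with fewer than three positive spike-ins
#' are a calibration failure.
#'
#' @param spikein_counts spike-in count table (samples x spike-ins).
#' @param design a [spikein_design()] giving added copies per spike-in.
#' @return data.frame with one row per sample: `sample_id`, slope `a`,
#'   intercept `b` (log10 reads), `r_squared`, `n_points`, and
#'   `dropped_spikeins` (comma-separated zero-read spike-ins).
#' @export
fit_standard_curves <- function(spikein_counts, design) {
  m <- unclass(spikein_counts)
  missing_sp <- setdiff(design$spikein_id, colnames(m))
  if (length(missing_sp) > 0L)
    stop("spike-ins in design absent from counts: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  m <- m[, design$spikein_id, drop = FALSE]
  x_all <- log10(design$added_copies)
  out <- lapply(seq_len(nrow(m)), function(i) {
    reads <- m[i, ]
    pos <- reads > 0
    if (sum(pos) < 3L)
      stop(sprintf("sample '%s': only %d spike-ins with reads > 0 (need >= 3)",
                   rownames(m)[i], sum(pos)), call. = FALSE)
    x <- x_all[pos]
    if (length(unique(x)) < 2L)
      stop(sprintf("sample '%s': zero variance in spike-in concentrations",
                   rownames(m)[i]), call. = FALSE)
    y <- log10(reads[pos])
    fit <- stats::lm.fit(cbind(1, x), y)
    b <- fit$coefficients[1]; a <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    data.frame(sample_id = rownames(m)[i], a = unname(a), b = unname(b),
               r_squared = r2, n_points = sum(pos),
               dropped_spikeins = paste(design$spikein_id[!pos],
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Convert biological read counts to absolute copies per liter
#'
#' Inverts each sample's standard curve: `Y_otu = 10^((log10(reads) - b)
#' / a)` for positive reads (zero reads map to zero copies), then
#' `AB_otu = Y_otu / (R * V)` in copies per liter.
#'
#' @param biological_counts cleaned biological [count_table()].
#' @param curves output of [fit_standard_curves()].
#' @param metadata [sample_metadata()] supplying `recovery_ratio` and
#'   `volume` per sample.
#' @return numeric matrix (samples x OTUs) of copies per liter, classed
#'   `htqs_quant`, with attributes `R` and `V`.
#' @export
estimate_absolute_abundance <- function(biological_counts, curves, metadata) {
  m <- unclass(biological_counts)
  ids <- rownames(m)
  miss <- setdiff(ids, curves$sample_id)
  if (length(miss) > 0L)
    stop("no standard curve for samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss) > 0L)
    stop("missing R/V metadata for samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cv <- curves[match(ids, curves$sample_id), ]
  md <- metadata[match(ids, metadata$sample_id), ]
  if (any(cv$a <= 0))
    stop("non-monotone standard curve (a <= 0) for samples: ",
         paste(ids[cv$a <= 0], collapse = ", "), call. = FALSE)
  quant <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    pos <- m[i, ] > 0
    y_otu <- 10^((log10(m[i, pos]) - cv$b[i]) / cv$a[i])
    quant[i, pos] <- y_otu / (md$recovery_ratio[i] * md$volume[i])
  }
  structure(quant, R = stats::setNames(md$recovery_ratio, ids),
            V = stats::setNames(md$volume, ids), class = "htqs_quant")
}

#' Rarefy a count table to a common depth
#'
#' Random subsampling without replacement; after rarefaction every sample
#' total equals `depth` exactly.
#'
#' @param counts a [count_table()].
#' @param depth integer target depth, or `"min"` for the smallest sample
#'   total.
#' @param seed integer seed (deterministic subsampling).
#' @return rarefied [count_table()].
#' @export
rarefy <- function(counts, depth = "min", seed = 1L) {
  m <- unclass(counts)
  totals <- rowSums(m)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  low <- totals < depth
  if (any(low))
    stop("samples with fewer reads than the rarefaction depth: ",
         paste(sprintf("%s (%d)", rownames(m)[low], totals[low]),
               collapse = ", "), call. = FALSE)
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (totals[i] == depth) next
    # draw read indices without replacement from the sample's read pool
    cum <- cumsum(m[i, ])
    idx <- sample.int(totals[i], depth)
    picked <- findInterval(idx - 1L, cum) + 1L
    out[i, ] <- tabulate(picked, nbins = ncol(m))
  }
  count_table(out)
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts a [count_table()] (or numeric abundance matrix).
#' @return matrix of proportions; rows of samples with reads sum to 1,
#'   all-zero samples stay zero with a warning.
#' @export
to_relative <- function(counts) {
  m <- unclass(counts)
  totals <- rowSums(m)
  if (any(totals == 0))
    warning("all-zero samples left as zeros: ",
            paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  res <- m / ifelse(totals == 0, 1, totals)
  storage.mode(res) <- "double"
  res
}

#' Per-sample total copies per liter with cohort summary
#'
#' @param quant output of [estimate_absolute_abundance()].
#' @return list with `totals` (named per-sample row sums) and `summary`
#'   (`min`, `mean`, `max`).
#' @export
summarize_totals <- function(quant) {
  totals <- rowSums(unclass(quant))
  list(totals = totals,
       summary = c(min = min(totals), mean = mean(totals),
                   max = max(totals)))
}
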