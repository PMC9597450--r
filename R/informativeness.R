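#' Percentage of polymorphic bands for an assay
#'
#' P% = 100 * PB / TAB, where PB is the number of polymorphic bands (unique
#' bands included) and TAB the total number of scored bands.
#'
#' @param summary One-row data frame from [summarize_assay()] (needs columns
#'   `n_polymorphic` and `n_total`).
#' @return Percentage in \[0, 100\], full precision (round for reporting).
#' @export
polymorphism_percent <- function(summary) {
  tab <- summary$n_total
  if (tab < 1)
    stop("polymorphism percentage undefined for an assay with no scored bands",
         call. = FALSE)
  100 * summary$n_polymorphic / tab
}

#' Band frequencies of an assay
#'
#' Fraction of genotypes carrying each scored band of the assay (bands absent
#' from every genotype are dropped, as they are never scored).
#'
#' @param x A [band_matrix].
#' @param assay_id Assay to use.
#' @return Numeric vector of frequencies in (0, 1\].
#' @export
band_frequencies <- function(x, assay_id) {
  rows <- .assay_rows(x, assay_id)
  f <- rowMeans(x$presence[rows, , drop = FALSE])
  f[f > 0]
}

#' Per-band polymorphism information content for a dominant marker
#'
#' For a dominant (presence/absence) band with carrier frequency `f`, the
#' per-band PIC is 2 f (1 - f), maximal (0.5) at f = 0.5 and zero for fixed
#' bands. The assay-level PIC in `per_band_mean` mode is the mean of this
#' quantity over the assay's scored bands.
#'
#' @param f Band (carrier) frequency in \[0, 1\]; vectorized.
#' @return 2 f (1 - f).
#' @export
pic_per_band <- function(f) {
  if (any(f < 0 | f > 1))
    stop("band frequency must lie in [0, 1]", call. = FALSE)
  2 * f * (1 - f)
}

#' Phenotype-frequency PIC of an assay
#'
#' Treats each genotype's multilocus banding pattern for the assay as one
#' phenotype class with frequency p_j and returns the Nei-style diversity
#' 1 - sum(p_j^2). Unlike the per-band formula this can exceed 0.5 (its
#' ceiling for n genotypes is 1 - 1/n), which is the behaviour of assay-level
#' PIC values reported for highly discriminating multiband primers.
#'
#' @param x A [band_matrix] with >= 2 genotypes.
#' @param assay_id Assay to use.
#' @return PIC in \[0, 1\).
#' @export
pic_phenotype <- function(x, assay_id) {
  rows <- .assay_rows(x, assay_id)
  if (length(x$genotypes) < 2L)
    stop("phenotype PIC needs at least two genotypes", call. = FALSE)
  pattern <- apply(x$presence[rows, , drop = FALSE], 2L, paste, collapse = "")
  p <- table(pattern) / length(pattern)
  1 - sum(p^2)
}

#' Effective multiplex ratio of an assay
#'
#' EMR = PB * (PB / TAB): the number of polymorphic bands weighted by the
#' polymorphic fraction. Equals TAB when every band is polymorphic.
#'
#' @inheritParams polymorphism_percent
#' @return EMR >= 0, full precision.
#' @export
emr <- function(summary) {
  tab <- summary$n_total
  if (tab < 1)
    stop("EMR undefined for an assay with no scored bands", call. = FALSE)
  pb <- summary$n_polymorphic
  pb * (pb / tab)
}

#' Marker index
#'
#' MI = PIC * EMR, using the unrounded PIC.
#'
#' @param pic Assay PIC (either mode), in \[0, 1\].
#' @param emr Effective multiplex ratio, >= 0.
#' @return MI >= 0.
#' @export
marker_index <- function(pic, emr) {
  stopifnot(is.finite(pic), is.finite(emr), pic >= 0, pic <= 1, emr >= 0)
  pic * emr
}

#' Resolving power of an assay
#'
#' Rp = sum over the assay's scored bands of the band informativeness
#' I_b = 1 - 2 * |0.5 - f_b|, where f_b is the fraction of genotypes carrying
#' band b. Each band contributes at most 1 (at f = 0.5) and fixed bands
#' contribute 0.
#'
#' @inheritParams band_frequencies
#' @return Rp >= 0.
#' @export
resolving_power <- function(x, assay_id) {
  f <- band_frequencies(x, assay_id)
  sum(1 - 2 * abs(0.5 - f))
}

#' Joined per-assay informativeness report
#'
#' One row per assay with band accounting (MB, UB, PB, TAB, fragment-size
#' range) and informativeness indices (PIC, EMR, MI, P%, Rp), followed by a
#' `Total` row (sums of counts; pooled P% = 100 * sum(PB) / sum(TAB)) and an
#' `Average` row (arithmetic means of the per-assay values, including the
#' mean P%). Values are full precision; round when writing report tables.
#'
#' @param x A [band_matrix].
#' @param pic_mode `"phenotype_freq"` (default; multilocus-pattern diversity
#'   1 - sum p^2) or `"per_band_mean"` (mean of 2f(1-f)). MI uses whichever
#'   mode is active.
#' @return Tibble with columns `assay_id`, `MB`, `UB`, `PB`, `TAB`,
#'   `FS_larger`, `FS_smaller`, `PIC`, `EMR`, `MI`, `P_percent`, `Rp`, plus
#'   attributes `mean_p_percent` and `pooled_p_percent`.
#' @export
informativeness_table <- function(x,
                                  pic_mode = c("phenotype_freq",
                                               "per_band_mean")) {
  pic_mode <- match.arg(pic_mode)
  ids <- assay_ids(x)
  rows <- lapply(ids, function(a) {
    s <- summarize_assay(x, a)
    pic <- if (pic_mode == "phenotype_freq") pic_phenotype(x, a)
           else mean(pic_per_band(band_frequencies(x, a)))
    e <- emr(s)
    tibble::tibble(
      assay_id = a, MB = s$n_monomorphic, UB = s$n_unique, PB = s$n_polymorphic,
      TAB = s$n_total, FS_larger = s$fs_max, FS_smaller = s$fs_min,
      PIC = pic, EMR = e, MI = marker_index(pic, e),
      P_percent = polymorphism_percent(s), Rp = resolving_power(x, a)
    )
  })
  per <- do.call(rbind, rows)
  pooled_p <- 100 * sum(per$PB) / sum(per$TAB)
  total <- tibble::tibble(
    assay_id = "Total", MB = sum(per$MB), UB = sum(per$UB), PB = sum(per$PB),
    TAB = sum(per$TAB), FS_larger = NA_real_, FS_smaller = NA_real_,
    PIC = sum(per$PIC), EMR = sum(per$EMR), MI = sum(per$MI),
    P_percent = pooled_p, Rp = sum(per$Rp)
  )
  average <- tibble::tibble(
    assay_id = "Average", MB = mean(per$MB), UB = mean(per$UB),
    PB = mean(per$PB), TAB = mean(per$TAB),
    FS_larger = NA_real_, FS_smaller = NA_real_,
    PIC = mean(per$PIC), EMR = mean(per$EMR), MI = mean(per$MI),
    P_percent = mean(per$P_percent), Rp = mean(per$Rp)
  )
  out <- rbind(per, total, average)
  attr(out, "mean_p_percent") <- mean(per$P_percent)
  attr(out, "pooled_p_percent") <- pooled_p
  attr(out, "pic_mode") <- pic_mode
  out
}

#' Write a report table as TSV with display rounding
#'
#' @param tbl Data frame (e.g. from [informativeness_table()]).
#' @param path Output path.
#' @param digits Display rounding for numeric columns (default 2); the
#'   in-memory tables always keep full precision.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(tbl, path, digits = 2) {
  stopifnot(digits >= 0)
  num <- vapply(tbl, is.numeric, logical(1L))
  tbl[num] <- lapply(tbl[num], round, digits = digits)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
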