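#' Construct a karyotype measurement set
#'
#' Holds per-chromosome short- and long-arm lengths for one genotype,
#' measured on the haploid complement. Arms are normalized on input so that
#' the long arm is the longer one; zero short arms (telocentric chromosomes)
#' are allowed.
#'
#' @param genotype Genotype label.
#' @param short_arm,long_arm Numeric vectors of arm lengths (micrometres),
#'   one entry per chromosome; each chromosome's total length must be > 0.
#' @param n_diploid Declared diploid chromosome number 2n; defaults to twice
#'   the number of measured chromosomes and is validated against it.
#' @return Object of class `karyotype_set`: list with `genotype`,
#'   `chromosomes` (tibble `index`, `short_arm`, `long_arm`) and `n_diploid`.
#' @export
#' @examples
#' k <- karyotype_set("G1", short_arm = c(2, 3), long_arm = c(5, 3.5))
#' karyotype_summary(k)
karyotype_set <- function(genotype, short_arm, long_arm, n_diploid = NULL) {
  stopifnot(length(short_arm) == length(long_arm))
  if (any(short_arm < 0) || any(long_arm < 0))
    stop("arm lengths must be non-negative", call. = FALSE)
  cl <- short_arm + long_arm
  if (any(cl <= 0))
    stop("degenerate chromosome with total length 0", call. = FALSE)
  s <- pmin(short_arm, long_arm)
  l <- pmax(short_arm, long_arm)
  n <- length(s)
  if (is.null(n_diploid)) n_diploid <- 2L * n
  if (n_diploid != 2L * n)
    stop("declared 2n (", n_diploid, ") does not equal twice the measured ",
         "haploid count (", n, ")", call. = FALSE)
  structure(
    list(genotype = as.character(genotype),
         chromosomes = tibble::tibble(index = seq_len(n), short_arm = s,
                                      long_arm = l),
         n_diploid = as.integer(n_diploid)),
    class = "karyotype_set"
  )
}

#' @export
print.karyotype_set <- function(x, ...) {
  cat(sprintf("karyotype_set: %s, %d haploid chromosomes (2n = %d)\n",
              x$genotype, nrow(x$chromosomes), x$n_diploid))
  invisible(x)
}

#' Read karyotype measurements from delimited text
#'
#' Columns `genotype,chromosome,short_arm_um,long_arm_um` (comma or tab).
#'
#' @param path File path.
#' @return Named list of [karyotype_set] objects, one per genotype.
#' @export
read_karyotypes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty karyotype file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE)
  sets <- lapply(split(tab, tab[[1L]]), function(d) {
    d <- d[order(d[[2L]]), ]
    karyotype_set(d[[1L]][1L], d[[3L]], d[[4L]])
  })
  sets[unique(as.character(tab[[1L]]))]
}

#' Write karyotype measurements to tab-delimited text
#'
#' @param sets List of [karyotype_set] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotypes <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(k) {
    data.frame(genotype = k$genotype, chromosome = k$chromosomes$index,
               short_arm_um = k$chromosomes$short_arm,
               long_arm_um = k$chromosomes$long_arm)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chromosome descriptors
#'
#' For each chromosome: total length CL = s + l, arm ratio r = l / s
#' (infinite for telocentrics), centromeric index ci = s / CL, and the
#' M-value (l - s) / CL used by Watanabe-style asymmetry.
#'
#' @param set A [karyotype_set].
#' @return Tibble with columns `index`, `short_arm`, `long_arm`, `CL`,
#'   `arm_ratio`, `ci`, `m_value`.
#' @export
chromosome_descriptors <- function(set) {
  s <- set$chromosomes$short_arm
  l <- set$chromosomes$long_arm
  cl <- s + l
  tibble::tibble(
    index = set$chromosomes$index, short_arm = s, long_arm = l, CL = cl,
    arm_ratio = ifelse(s > 0, l / s, Inf),
    ci = s / cl,
    m_value = (l - s) / cl
  )
}

#' Default Levan-style arm-ratio class boundaries
#'
#' Upper arm-ratio bounds for the "nearly metacentric" (nm), "nearly
#' submetacentric" (nsm (-)) and "nearly subtelocentric" (nst) classes;
#' ratios at or above the last bound are "nearly telocentric" (nt).
#' @export
levan_thresholds <- c(nm = 1.7, `nsm (-)` = 3.0, nst = 7.0)

#' Classify chromosomes by arm ratio
#'
#' Levan-style bands on the arm ratio r = long/short: nm for 1 <= r < 1.7,
#' nsm (-) for 1.7 <= r < 3, nst for 3 <= r < 7, nt for r >= 7 (telocentric
#' chromosomes, r infinite, are nt).
#'
#' @param set A [karyotype_set].
#' @param thresholds Named numeric vector of upper bounds as in
#'   [levan_thresholds]; must be strictly increasing.
#' @return Character vector of class tags, one per chromosome.
#' @export
classify_chromosomes <- function(set, thresholds = levan_thresholds) {
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds, strictly = TRUE))
  r <- chromosome_descriptors(set)$arm_ratio
  cls <- character(length(r))
  cls[r < thresholds[[1L]]] <- names(thresholds)[1L]
  cls[r >= thresholds[[1L]] & r < thresholds[[2L]]] <- names(thresholds)[2L]
  cls[r >= thresholds[[2L]] & r < thresholds[[3L]]] <- names(thresholds)[3L]
  cls[r >= thresholds[[3L]]] <- "nt"
  cls
}

#' Karyotype formula
#'
#' Diploid counts of chromosomes per centromere class rendered as
#' `"<count> <class>"` joined by `"+"`, in the fixed class order
#' nsm (-), nst, nm, nt; classes with zero count are omitted. Counts are
#' twice the haploid tallies, so they sum to 2n.
#'
#' @inheritParams classify_chromosomes
#' @return Formula string, e.g. `"2 nsm (-)+12 nst+12 nm"`.
#' @export
karyotype_formula <- function(set, thresholds = levan_thresholds) {
  cls <- classify_chromosomes(set, thresholds)
  order <- c("nsm (-)", "nst", "nm", "nt")
  counts <- 2L * vapply(order, function(k) sum(cls == k), integer(1L))
  keep <- counts > 0L
  paste(paste(counts[keep], order[keep]), collapse = "+")
}

#' Stebbins two-way symmetry category
#'
#' Column letter from the chromosome-length ratio R = max(CL) / min(CL):
#' A if R < 2, B if 2 <= R < 4, C if R >= 4. Row digit from the proportion P
#' of chromosomes with arm ratio > 2: 1 if P = 0, 2 if 0 < P <= 0.5,
#' 3 if 0.5 < P < 1, 4 if P = 1. Telocentric chromosomes count as arm
#' ratio > 2.
#'
#' @param set A [karyotype_set] with >= 2 chromosomes.
#' @return Category string such as `"2B"`.
#' @export
stebbins_category <- function(set) {
  d <- chromosome_descriptors(set)
  if (nrow(d) < 2L)
    stop("Stebbins category needs at least two chromosomes", call. = FALSE)
  R <- max(d$CL) / min(d$CL)
  P <- mean(d$arm_ratio > 2)
  col <- if (R < 2) "A" else if (R < 4) "B" else "C"
  row <- if (P == 0) "1" else if (P <= 0.5) "2" else if (P < 1) "3" else "4"
  paste0(row, col)
}

#' Full karyotype summary
#'
#' Computes, from the haploid measurement set:
#' \itemize{
#'   \item `HCL` total haploid complement length (sum of CL, um);
#'   \item `TF_percent` total form percentage, 100 * sum(s) / sum(CL), and its
#'     complement `AsK_percent` = 100 * sum(l) / sum(CL) (karyotype asymmetry
#'     index); the two always sum to 100;
#'   \item `S_percent` Arano symmetry, 100 * min(CL) / max(CL);
#'   \item `CI` mean centromeric index;
#'   \item `A` Watanabe degree of asymmetry, mean of (l - s)/(l + s), and
#'     `MCA` = 100 * A (mean centromeric asymmetry);
#'   \item `CVcl`, `CVci` coefficients of variation (percent) of chromosome
#'     length and centromeric index;
#'   \item `A1` Romero-Zarco intrachromosomal index 1 - mean(s/l) (telocentric
#'     s/l terms contribute 0) and `A2` interchromosomal index = CVcl / 100;
#'   \item `AI` asymmetry index CVcl * CVci / 100;
#'   \item Stebbins category and karyotype formula.
#' }
#' All values are returned at full precision; round to 2 decimals for report
#' tables.
#'
#' @param set A [karyotype_set] with >= 2 chromosomes.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`
#'   for the CVs.
#' @param thresholds Arm-ratio class bounds for the formula, see
#'   [classify_chromosomes()].
#' @return One-row tibble with columns `genotype`, `n_diploid`, `HCL`,
#'   `TF_percent`, `AsK_percent`, `S_percent`, `CI`, `A`, `MCA`, `CVcl`,
#'   `CVci`, `AI`, `stebbins`, `A1`, `A2`, `formula`.
#' @export
karyotype_summary <- function(set, sd_type = c("sample", "population"),
                              thresholds = levan_thresholds) {
  sd_type <- match.arg(sd_type)
  d <- chromosome_descriptors(set)
  n <- nrow(d)
  if (n < 2L)
    stop("CV-based karyotype indices need at least two chromosomes",
         call. = FALSE)
  sdev <- function(v) {
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  tf <- 100 * sum(d$short_arm) / sum(d$CL)
  a <- mean(d$m_value)
  cvcl <- 100 * sdev(d$CL) / mean(d$CL)
  cvci <- 100 * sdev(d$ci) / mean(d$ci)
  tibble::tibble(
    genotype = set$genotype,
    n_diploid = set$n_diploid,
    HCL = sum(d$CL),
    TF_percent = tf,
    AsK_percent = 100 - tf,
    S_percent = 100 * min(d$CL) / max(d$CL),
    CI = mean(d$ci),
    A = a,
    MCA = 100 * a,
    CVcl = cvcl,
    CVci = cvci,
    AI = cvcl * cvci / 100,
    stebbins = stebbins_category(set),
    A1 = 1 - mean(ifelse(d$long_arm > 0, d$short_arm / d$long_arm, 0)),
    A2 = cvcl / 100,
    formula = karyotype_formula(set, thresholds)
  )
}

#' Ideogram drawing coordinates
#'
#' Cumulative coordinates per chromosome for ideogram rendering: 0 at the
#' short-arm telomere, centromere at s, end at CL.
#'
#' @param set A [karyotype_set].
#' @param order `"by_length"` (descending total length, default) or
#'   `"by_index"`.
#' @return Tibble with columns `slot` (drawing position), `index`,
#'   `short_arm`, `long_arm`, `centromere`, `end`.
#' @export
ideogram_table <- function(set, order = c("by_length", "by_index")) {
  order <- match.arg(order)
  d <- chromosome_descriptors(set)
  o <- if (order == "by_length") order(-d$CL, d$index) else order(d$index)
  d <- d[o, ]
  tibble::tibble(
    slot = seq_len(nrow(d)), index = d$index,
    short_arm = d$short_arm, long_arm = d$long_arm,
    centromere = d$short_arm, end = d$CL
  )
}

#' Export an ideogram as SVG
#'
#' Simple haploid-ideogram rendering: one vertical bar per chromosome,
#' short arm above the centromere notch, chromosomes in the order of
#' [ideogram_table()].
#'
#' @inheritParams ideogram_table
#' @param path Output SVG path.
#' @param bar_width,gap Bar width and spacing in user units.
#' @return `path`, invisibly.
#' @export
write_ideogram_svg <- function(set, path, order = "by_length",
                               bar_width = 14, gap = 10) {
  tab <- ideogram_table(set, order)
  scale <- 300 / max(tab$end)
  width <- nrow(tab) * (bar_width + gap) + gap
  height <- 360
  rect <- function(x, y, w, h, fill) {
    sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" stroke="black" stroke-width="0.5"/>',
            x, y, w, h, fill)
  }
  elems <- character(0)
  for (i in seq_len(nrow(tab))) {
    x <- gap + (i - 1) * (bar_width + gap)
    s <- tab$short_arm[i] * scale
    l <- tab$long_arm[i] * scale
    top <- 20 + (300 - s - l) / 2
    elems <- c(elems,
               rect(x, top, bar_width, s, "#9ecae1"),
               rect(x, top + s, bar_width, l, "#3182bd"),
               sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black"/>',
                       x - 2, top + s, x + bar_width + 2, top + s),
               sprintf('<text x="%.2f" y="%.2f" font-size="8" text-anchor="middle">%d</text>',
                       x + bar_width / 2, 340, tab$index[i]))
  }
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   ceiling(width), height),
           sprintf('<text x="%.2f" y="14" font-size="10">%s</text>',
                   gap, set$genotype),
           elems, "</svg>")
  writeLines(svg, path)
  invisible(path)
}
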