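#' Dominant-marker allele frequencies at one locus
#'
#' A dominant band cannot distinguish homozygous from heterozygous carriers,
#' so the band-absent (recessive) allele frequency is recovered assuming
#' Hardy-Weinberg equilibrium: q = sqrt(1 - f), p = 1 - q, where f is the
#' fraction of the population's individuals carrying the band.
#'
#' @param x A [band_matrix] whose columns are individuals.
#' @param members Character vector of individual column labels forming the
#'   population.
#' @param locus Band row index (or a `(assay_id, band_id)` key pasted with
#'   `"/"`) identifying the locus.
#' @return List with elements `f`, `q`, `p`.
#' @export
dominant_allele_freqs <- function(x, members, locus) {
  missing <- setdiff(members, x$genotypes)
  if (length(missing))
    stop("unknown individuals: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!length(members)) stop("empty population", call. = FALSE)
  if (is.character(locus)) {
    key <- paste(x$bands$assay_id, x$bands$band_id, sep = "/")
    locus <- match(locus, key)
  }
  if (is.na(locus) || locus < 1 || locus > nrow(x$bands))
    stop("unknown locus", call. = FALSE)
  f <- mean(x$presence[locus, members])
  q <- sqrt(1 - f)
  list(f = f, q = q, p = 1 - q)
}

#' Per-locus diversity statistics for dominant data
#'
#' Given Hardy-Weinberg allele frequencies p (dominant) and q (recessive) at
#' one locus and the number of individuals N:
#' Na = number of alleles segregating (frequency > 0, so 1 or 2);
#' Ne = 1 / (p^2 + q^2) (effective allele number);
#' I  = -(p ln p + q ln q) (Shannon index, nats; 0 ln 0 = 0);
#' He = 2 p q (expected heterozygosity);
#' uHe = 2N / (2N - 1) * He (unbiased correction).
#'
#' @param p Dominant-allele frequency.
#' @param q Recessive-allele frequency (p + q = 1).
#' @param N Number of individuals in the population (>= 1).
#' @return Named list `Na`, `Ne`, `I`, `He`, `uHe`.
#' @export
locus_statistics <- function(p, q, N) {
  stopifnot(N >= 1, abs(p + q - 1) < 1e-12, p >= 0, q >= 0)
  xlx <- function(z) ifelse(z > 0, z * log(z), 0)
  he <- 2 * p * q
  list(
    Na = sum(c(p, q) > 0),
    Ne = 1 / (p^2 + q^2),
    I = -(xlx(p) + xlx(q)),
    He = he,
    uHe = (2 * N) / (2 * N - 1) * he
  )
}

#' Read an individual-to-population map
#'
#' Delimited text (comma or tab) with columns `individual,population`.
#'
#' @param path File path.
#' @return Named list of character vectors: population label -> members.
#' @export
read_population_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty population map: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character")
  split(tab[[1L]], tab[[2L]])
}

#' Population-genetic summary over all loci
#'
#' Averages the per-locus statistics of [locus_statistics()] over every band
#' (locus) in the matrix for each population, following the binary-data
#' convention of averaging over all loci: a locus fixed for band absence
#' within a population still contributes Na = 1, Ne = 1, He = 0. The
#' polymorphism percentage counts loci with 0 < f < 1 within the population.
#' A final `Total` row holds the mean over populations.
#'
#' @param x A [band_matrix] whose columns are individuals.
#' @param pops Named list mapping population label -> member column labels
#'   (as returned by [read_population_map()]).
#' @return Tibble with columns `population`, `N`, `Na`, `Ne`, `I`, `He`,
#'   `uHe`, `p_percent`.
#' @export
popgen_summary <- function(x, pops) {
  if (!nrow(x$bands))
    stop("population summary undefined with no loci", call. = FALSE)
  if (is.null(names(pops)) || any(!nzchar(names(pops))))
    stop("populations must be named", call. = FALSE)
  rows <- lapply(names(pops), function(lab) {
    members <- pops[[lab]]
    if (!length(members)) stop("empty population: ", lab, call. = FALSE)
    N <- length(members)
    stats <- lapply(seq_len(nrow(x$bands)), function(i) {
      fr <- dominant_allele_freqs(x, members, i)
      c(unlist(locus_statistics(fr$p, fr$q, N)), poly = fr$f > 0 && fr$f < 1)
    })
    m <- colMeans(do.call(rbind, stats))
    tibble::tibble(population = lab, N = N, Na = m[["Na"]], Ne = m[["Ne"]],
                   I = m[["I"]], He = m[["He"]], uHe = m[["uHe"]],
                   p_percent = 100 * m[["poly"]])
  })
  per <- do.call(rbind, rows)
  total <- tibble::tibble(
    population = "Total", N = sum(per$N), Na = mean(per$Na), Ne = mean(per$Ne),
    I = mean(per$I), He = mean(per$He), uHe = mean(per$uHe),
    p_percent = mean(per$p_percent)
  )
  rbind(per, total)
}

#' Harvest index
#'
#' Seed yield as a percentage of biological yield, where biological yield is
#' seed plus stover: 100 * seed / (seed + stover).
#'
#' @param seed_yield Seed yield (mass per area), >= 0.
#' @param stover_yield Stover yield (same units), >= 0.
#' @return Percentage in \[0, 100\].
#' @export
harvest_index <- function(seed_yield, stover_yield) {
  stopifnot(seed_yield >= 0, stover_yield >= 0)
  total <- seed_yield + stover_yield
  if (any(total == 0))
    stop("harvest index undefined when seed and stover yields are both zero",
         call. = FALSE)
  100 * seed_yield / total
}
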