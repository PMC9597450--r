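#' Specify a synthetic dominant-marker assay
#'
#' Describes the band-class composition of one assay so that
#' [generate_band_matrix()] can construct a band matrix whose
#' [summarize_assay()] output reproduces the specification exactly:
#' `n_monomorphic` bands present in every genotype, `n_unique_pos` present in
#' exactly one, `n_unique_neg` absent from exactly one, and
#' `n_other_polymorphic` with presence counts drawn uniformly from the
#' feasible range 2..(n_genotypes - 2) (so they can never collapse into
#' unique or monomorphic classes).
#'
#' @param assay_id Assay label.
#' @param n_genotypes Number of genotype columns (>= 2; >= 4 when
#'   `n_other_polymorphic` > 0).
#' @param n_monomorphic,n_unique_pos,n_unique_neg,n_other_polymorphic
#'   Non-negative band counts per class.
#' @param fs_range Length-2 integer range fragment sizes are sampled from,
#'   without replacement (band identities stay unique; sizes carry no
#'   statistical role).
#' @return List of class `assay_spec`.
#' @export
assay_spec <- function(assay_id, n_genotypes, n_monomorphic = 0,
                       n_unique_pos = 0, n_unique_neg = 0,
                       n_other_polymorphic = 0, fs_range = c(75L, 2150L)) {
  counts <- c(n_monomorphic, n_unique_pos, n_unique_neg, n_other_polymorphic)
  if (any(counts < 0)) stop("band counts must be non-negative", call. = FALSE)
  if (n_genotypes < 2L)
    stop("infeasible spec: need at least two genotypes", call. = FALSE)
  if (n_unique_neg > 0 && n_genotypes < 3L)
    stop("infeasible spec: with two genotypes a negative-unique pattern is ",
         "indistinguishable from a positive-unique one", call. = FALSE)
  if (n_other_polymorphic > 0 && n_genotypes < 4L)
    stop("infeasible spec: non-unique polymorphic bands need >= 4 genotypes ",
         "(presence counts 2..n-2)", call. = FALSE)
  total <- sum(counts)
  if (total < 1L) stop("infeasible spec: no bands", call. = FALSE)
  if (diff(fs_range) + 1L < total)
    stop("fragment-size range too narrow for ", total, " distinct sizes",
         call. = FALSE)
  structure(
    list(assay_id = as.character(assay_id), n_genotypes = as.integer(n_genotypes),
         n_monomorphic = as.integer(n_monomorphic),
         n_unique_pos = as.integer(n_unique_pos),
         n_unique_neg = as.integer(n_unique_neg),
         n_other_polymorphic = as.integer(n_other_polymorphic),
         n_total = as.integer(total), fs_range = as.integer(fs_range)),
    class = "assay_spec"
  )
}

#' Generate a band matrix matching assay specifications exactly
#'
#' Constructive generator: each assay of the result, when passed through
#' [summarize_assay()], returns exactly the MB/UB/PB/TAB counts of its
#' [assay_spec()]. "Other polymorphic" presence patterns are drawn with
#' carrier counts uniform on 2..(n - 2), and the carriers themselves are a
#' uniform random subset, so band frequencies vary while class counts stay
#' exact. Generation is deterministic under `seed`.
#'
#' @param specs An [assay_spec] or list of them; all must agree on
#'   `n_genotypes`.
#' @param genotypes Optional genotype labels (default `G1..Gn`).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param unit Size unit tag for the result.
#' @return A [band_matrix].
#' @export
generate_band_matrix <- function(specs, genotypes = NULL, seed = 1L,
                                 unit = "bp") {
  if (inherits(specs, "assay_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  n <- unique(vapply(specs, function(s) s$n_genotypes, integer(1L)))
  if (length(n) != 1L)
    stop("all assay specs must share one genotype count", call. = FALSE)
  if (is.null(genotypes)) genotypes <- paste0("G", seq_len(n))
  stopifnot(length(genotypes) == n)
  ids <- vapply(specs, function(s) s$assay_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate assay ids in specs", call. = FALSE)
  withr::with_seed(seed, {
    parts <- lapply(specs, function(sp) {
      pres <- matrix(0L, nrow = 0L, ncol = n)
      add <- function(rows) pres <<- rbind(pres, rows)
      if (sp$n_monomorphic > 0)
        add(matrix(1L, sp$n_monomorphic, n))
      if (sp$n_unique_pos > 0) {
        rows <- matrix(0L, sp$n_unique_pos, n)
        rows[cbind(seq_len(sp$n_unique_pos),
                   sample.int(n, sp$n_unique_pos, replace = TRUE))] <- 1L
        add(rows)
      }
      if (sp$n_unique_neg > 0) {
        rows <- matrix(1L, sp$n_unique_neg, n)
        rows[cbind(seq_len(sp$n_unique_neg),
                   sample.int(n, sp$n_unique_neg, replace = TRUE))] <- 0L
        add(rows)
      }
      if (sp$n_other_polymorphic > 0) {
        rows <- t(vapply(seq_len(sp$n_other_polymorphic), function(i) {
          counts <- 2:(n - 2L)
          k <- counts[sample.int(length(counts), 1L)]
          r <- integer(n)
          r[sample.int(n, k)] <- 1L
          r
        }, integer(n)))
        add(rows)
      }
      fs <- sort(sample(sp$fs_range[1L]:sp$fs_range[2L], sp$n_total),
                 decreasing = TRUE)
      list(bands = data.frame(assay_id = sp$assay_id,
                              band_id = as.character(fs),
                              fragment_size = fs),
           presence = pres)
    })
    band_matrix(
      genotypes = genotypes,
      bands = do.call(rbind, lapply(parts, `[[`, "bands")),
      presence = do.call(rbind, lapply(parts, `[[`, "presence")),
      unit = unit
    )
  })
}

#' Expand genotype profiles into replicated individuals
#'
#' Turns a per-genotype band matrix into a per-individual matrix by
#' replicating each genotype column and flipping each cell independently
#' with a small probability, emulating within-genotype scoring variation.
#' Column labels `<genotype>_r<k>` encode membership for the population map.
#'
#' @param x A [band_matrix] whose columns are genotypes.
#' @param replicates Individuals per genotype (>= 1).
#' @param flip_rate Per-cell flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return List with `matrix` (the individual-level [band_matrix]) and
#'   `populations` (named list genotype -> individual labels, ready for
#'   [popgen_summary()]).
#' @export
generate_population_samples <- function(x, replicates, flip_rate = 0,
                                        seed = 1L) {
  stopifnot(replicates >= 1L)
  if (flip_rate < 0 || flip_rate >= 0.5)
    stop("flip rate must lie in [0, 0.5)", call. = FALSE)
  withr::with_seed(seed, {
    cols <- rep(seq_along(x$genotypes), each = replicates)
    pres <- x$presence[, cols, drop = FALSE]
    labels <- paste0(rep(x$genotypes, each = replicates), "_r",
                     rep(seq_len(replicates), length(x$genotypes)))
    if (flip_rate > 0) {
      flips <- matrix(stats::runif(length(pres)) < flip_rate, nrow(pres))
      pres[flips] <- 1L - pres[flips]
    }
    out <- band_matrix(labels, x$bands, pres, unit = x$unit)
    pops <- split(labels, rep(x$genotypes, each = replicates))
    list(matrix = out, populations = pops[x$genotypes])
  })
}

#' Generate a karyotype hitting summary targets exactly
#'
#' Constructive generator for chromosome arm measurements:
#' \itemize{
#'   \item `tf_percent` mode: every chromosome is split with short-arm
#'     fraction `tf_percent / 100`, so the pooled TF% (and hence AsK% =
#'     100 - TF%) of [karyotype_summary()] is exact by construction;
#'   \item `m_value` mode: every chromosome satisfies
#'     (l - s) / (l + s) = `m_value`, so Watanabe's A and MCA = 100 A are
#'     exact;
#'   \item `cv_percent` mode: chromosome lengths form a two-point set whose
#'     sample coefficient of variation is solved numerically to the target
#'     (within 1e-9), fixing A2 = CVcl / 100.
#' }
#' `tf_percent` and `m_value` are two parameterizations of the same arm
#' split and cannot be combined; either can be combined with `cv_percent`
#' (lengths and splits are orthogonal). With `cv_percent` alone, arms are
#' split at a fixed default M-value of 0.15. With neither arm target, and in
#' the length dimension when `cv_percent` is absent, values are drawn
#' randomly (seeded), then scaled to `total_length`.
#'
#' @param n_chromosomes Haploid chromosome count (>= 2).
#' @param total_length Haploid complement length in micrometres.
#' @param tf_percent Pooled short-arm percentage target in (0, 50\].
#' @param m_value Uniform per-chromosome (l - s)/(l + s) target in \[0, 1).
#' @param cv_percent Target chromosome-length CV (percent, sample sd).
#' @param genotype Label for the resulting set.
#' @param seed Integer seed.
#' @return A [karyotype_set].
#' @export
generate_karyotype <- function(n_chromosomes = 13L, total_length = 100,
                               tf_percent = NULL, m_value = NULL,
                               cv_percent = NULL, genotype = "synthetic",
                               seed = 1L) {
  stopifnot(n_chromosomes >= 2L, total_length > 0)
  if (!is.null(tf_percent) && !is.null(m_value))
    stop("tf_percent and m_value both fix the arm split; give only one",
         call. = FALSE)
  if (!is.null(tf_percent) && (tf_percent <= 0 || tf_percent > 50))
    stop("infeasible target: TF% must lie in (0, 50]", call. = FALSE)
  if (!is.null(m_value) && (m_value < 0 || m_value >= 1))
    stop("infeasible target: M-value must lie in [0, 1)", call. = FALSE)
  if (!is.null(cv_percent) && cv_percent < 0)
    stop("infeasible target: CV must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    n <- n_chromosomes
    lengths <- if (is.null(cv_percent)) {
      stats::runif(n, 0.5, 1.5)
    } else {
      .two_point_cv(n, cv_percent)
    }
    lengths <- lengths * total_length / sum(lengths)
    frac <- if (!is.null(tf_percent)) {
      rep(tf_percent / 100, n)
    } else {
      m <- if (!is.null(m_value)) m_value
           else if (!is.null(cv_percent)) 0.15
           else NULL
      if (!is.null(m)) rep((1 - m) / 2, n)
      else stats::runif(n, 0.25, 0.5)
    }
    karyotype_set(genotype, short_arm = lengths * frac,
                  long_arm = lengths * (1 - frac))
  })
}

# two-point length set c(rep(a, k), rep(1, n - k)) with sample CV = target %
.two_point_cv <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  k <- n %/% 2L
  cv_of <- function(a) {
    v <- c(rep(a, k), rep(1, n - k))
    100 * stats::sd(v) / mean(v)
  }
  # supremum as a -> Inf: CV of the indicator vector
  limit <- 100 * sqrt(n * (n - k) / (k * (n - 1)))
  if (cv_percent >= limit * 0.999)
    stop("infeasible target: two-point CV with ", n,
         " chromosomes cannot exceed ", sprintf("%.1f%%", limit),
         call. = FALSE)
  upper <- 2
  while (cv_of(upper) < cv_percent) upper <- upper * 2
  a <- stats::uniroot(function(a) cv_of(a) - cv_percent, c(1, upper),
                      tol = .Machine$double.eps^0.75)$root
  c(rep(a, k), rep(1, n - k))
}
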