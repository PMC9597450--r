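# Published per-primer band-class counts (MB, UB, PB, TAB) for a 20-primer
# ISSR panel and a 25-primer SCoT panel scored over six sesame genotypes;
# used to reconstruct fixtures whose accounting is exact. UB is placed
# entirely in the positive-unique class (the split is irrelevant to every
# index computed from these counts).

issr_counts <- function() {
  data.frame(
    assay_id = paste0("ISSR", 1:20),
    MB = c(6, 0, 2, 5, 1, 1, 4, 5, 0, 0, 7, 10, 4, 2, 1, 6, 6, 3, 4, 5),
    UB = c(3, 9, 0, 0, 6, 8, 3, 2, 3, 6, 2, 2, 3, 4, 3, 0, 0, 4, 2, 2),
    PB = c(8, 19, 4, 1, 12, 13, 9, 6, 7, 17, 2, 4, 10, 11, 12, 4, 3, 7, 6, 6),
    TAB = c(14, 19, 6, 6, 13, 14, 13, 11, 7, 17, 9, 14, 14, 13, 13, 10, 9,
            10, 10, 11)
  )
}

scot_counts <- function() {
  data.frame(
    assay_id = paste0("SCoT", 1:25),
    MB = c(4, 2, 4, 0, 6, 1, 8, 2, 4, 1, 2, 0, 2, 0, 1, 6, 2, 2, 2, 2, 0,
           5, 1, 4, 0),
    UB = c(1, 0, 0, 5, 0, 6, 1, 2, 1, 2, 5, 1, 2, 4, 2, 1, 1, 0, 1, 2, 18,
           5, 3, 2, 11),
    PB = c(5, 8, 2, 13, 3, 7, 5, 7, 5, 4, 8, 12, 6, 10, 8, 4, 7, 4, 9, 9,
           31, 9, 13, 7, 18),
    TAB = c(9, 10, 6, 13, 9, 8, 13, 9, 9, 5, 10, 12, 8, 10, 9, 10, 9, 6,
            11, 11, 31, 14, 14, 11, 18)
  )
}

# assay specs reproducing a count table over a 6-genotype roster
specs_from_counts <- function(counts, n_genotypes = 6L) {
  lapply(seq_len(nrow(counts)), function(i) {
    assay_spec(counts$assay_id[i], n_genotypes,
               n_monomorphic = counts$MB[i],
               n_unique_pos = counts$UB[i],
               n_other_polymorphic = counts$PB[i] - counts$UB[i])
  })
}

# band matrix with hand-chosen presence patterns for direct arithmetic
small_band_matrix <- function() {
  band_matrix(
    genotypes = paste0("G", 1:6),
    bands = data.frame(
      assay_id = rep(c("P1", "P2"), c(4, 3)),
      band_id = as.character(c(900, 700, 500, 300, 450, 250, 150)),
      fragment_size = c(900, 700, 500, 300, 450, 250, 150)
    ),
    presence = rbind(
      c(1, 1, 1, 1, 1, 1),  # monomorphic (f = 1)
      c(1, 1, 1, 0, 0, 0),  # f = 1/2
      c(1, 0, 0, 0, 0, 0),  # unique_pos (f = 1/6)
      c(1, 1, 1, 1, 1, 0),  # unique_neg (f = 5/6)
      c(1, 1, 1, 1, 1, 1),
      c(0, 0, 1, 1, 0, 0),
      c(1, 1, 0, 0, 1, 1)
    )
  )
}

# rule-based classification oracle, evaluated directly from the definitions
ref_classify <- function(pattern) {
  n <- length(pattern)
  carriers <- sum(pattern == 1)
  if (carriers == n) return("monomorphic")
  if (carriers == 0) return("absent")
  if (carriers == 1) return("unique_pos")
  if (n - carriers == 1) return("unique_neg")
  "polymorphic_other"
}

# brute-force UPGMA reference: cluster distances recomputed each step as the
# mean over all cross pairs of the ORIGINAL distance matrix; ties broken by
# smallest member label. Returns the implied cophenetic distance matrix.
ref_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1L):length(clusters)) {
        dist_ab <- mean(d[clusters[[a]], clusters[[b]]])
        key <- sort(labs[c(clusters[[a]], clusters[[b]])])[1:2]
        if (is.null(best) || dist_ab < best$d - 1e-15 ||
            (abs(dist_ab - best$d) <= 1e-15 &&
             paste(key, collapse = "\r") < paste(best$key, collapse = "\r"))) {
          best <- list(a = a, b = b, d = dist_ab, key = key)
        }
      }
    }
    for (i in clusters[[best$a]]) for (j in clusters[[best$b]]) {
      coph[i, j] <- coph[j, i] <- best$d
    }
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  coph
}

# Procrustes residual after centering and optimal rotation/reflection
# (no scaling): sqrt of the summed squared coordinate differences.
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  rot <- s$u %*% t(s$v)
  sqrt(sum((X - Y %*% rot)^2))
}

# formula-by-formula karyotype oracle, independent of karyotype_summary()
ref_karyotype_indices <- function(s, l) {
  cl <- s + l
  ci <- s / cl
  list(
    HCL = sum(cl),
    TF_percent = 100 * sum(s) / sum(cl),
    AsK_percent = 100 * sum(l) / sum(cl),
    S_percent = 100 * min(cl) / max(cl),
    CI = mean(ci),
    A = mean((l - s) / (l + s)),
    MCA = 100 * mean((l - s) / (l + s)),
    CVcl = 100 * sd(cl) / mean(cl),
    CVci = 100 * sd(ci) / mean(ci),
    A1 = 1 - mean(s / l),
    A2 = sd(cl) / mean(cl)
  )
}

random_karyotype <- function(n = 13) {
  s <- runif(n, 0.5, 5)
  l <- s * runif(n, 1, 6)
  karyotype_set("rk", s, l)
}
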