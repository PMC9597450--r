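#' Construct a binary band matrix
#'
#' A `band_matrix` holds presence/absence (1/0) scores for bands amplified by
#' dominant marker assays (ISSR, SCoT primers) or resolved on SDS-PAGE protein
#' gels, across an ordered roster of genotypes. Bands are grouped by the assay
#' (primer or gel) that produced them and keyed by fragment size.
#'
#' @param genotypes Character vector of genotype (column) labels, length >= 1,
#'   no duplicates.
#' @param bands Data frame with columns `assay_id` (character), `band_id`
#'   (character) and `fragment_size` (positive number, bp or kDa per `unit`).
#'   `(assay_id, band_id)` pairs must be unique.
#' @param presence Integer or numeric matrix of 0/1 values, one row per band,
#'   one column per genotype.
#' @param unit Size unit of `fragment_size`: `"bp"` for DNA fingerprints,
#'   `"kDa"` for protein profiles.
#'
#' @return An object of class `band_matrix`: a list with elements `genotypes`,
#'   `bands` (tibble), `presence` (integer matrix with genotype column names)
#'   and `unit`.
#' @export
#' @examples
#' bm <- band_matrix(
#'   genotypes = c("G1", "G2", "G3"),
#'   bands = data.frame(assay_id = "P1", band_id = c("500", "300"),
#'                      fragment_size = c(500, 300)),
#'   presence = rbind(c(1, 1, 1), c(1, 0, 1))
#' )
#' n_bands(bm)
band_matrix <- function(genotypes, bands, presence, unit = c("bp", "kDa")) {
  unit <- match.arg(unit)
  genotypes <- as.character(genotypes)
  bands <- tibble::as_tibble(bands)
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  x <- structure(
    list(genotypes = genotypes, bands = bands, presence = presence,
         unit = unit),
    class = "band_matrix"
  )
  validate_band_matrix(x)
}

validate_band_matrix <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  if (length(x$genotypes) < 1L)
    stop("band_matrix needs at least one genotype", call. = FALSE)
  if (anyDuplicated(x$genotypes))
    stop("duplicate genotype labels", call. = FALSE)
  need <- c("assay_id", "band_id", "fragment_size")
  if (!all(need %in% names(x$bands)))
    stop("`bands` must have columns assay_id, band_id, fragment_size",
         call. = FALSE)
  if (nrow(x$bands) != nrow(x$presence))
    stop("presence matrix rows must match band records", call. = FALSE)
  if (ncol(x$presence) != length(x$genotypes))
    stop("presence matrix columns must match genotype roster", call. = FALSE)
  if (nrow(x$presence) && !all(x$presence %in% c(0L, 1L)))
    stop("presence cells must all be 0 or 1", call. = FALSE)
  if (any(x$bands$fragment_size <= 0))
    stop("fragment sizes must be positive", call. = FALSE)
  key <- paste(x$bands$assay_id, x$bands$band_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x$bands[duplicated(key), c("assay_id", "band_id")]
    stop("duplicate band identity (assay_id, band_id): ",
         paste(d$assay_id, d$band_id, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  colnames(x$presence) <- x$genotypes
  x
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d bands x %d genotypes (%d assays, unit %s)\n",
              nrow(x$bands), length(x$genotypes),
              length(unique(x$bands$assay_id)), x$unit))
  invisible(x)
}

#' @rdname band_matrix
#' @param x A `band_matrix`.
#' @export
n_bands <- function(x) nrow(x$bands)

#' @rdname band_matrix
#' @export
assay_ids <- function(x) unique(x$bands$assay_id)

# rows of a given assay, with existence check
.assay_rows <- function(x, assay_id) {
  rows <- which(x$bands$assay_id == assay_id)
  if (!length(rows))
    stop("unknown assay_id: ", assay_id, call. = FALSE)
  rows
}

#' Read a band matrix from delimited text
#'
#' Expects a header row `assay_id,band_id,fragment_size,<genotype1>,...` and
#' one row per scored band. The field separator (comma or tab) is
#' autodetected from the header. Genotype order is preserved from the header.
#'
#' @param path Path to the file.
#' @param unit Size unit tag, `"bp"` or `"kDa"`.
#' @return A validated [band_matrix].
#' @export
read_band_matrix <- function(path, unit = c("bp", "kDa")) {
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop("band-matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty band-matrix file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 4L)
    stop("band-matrix file needs assay_id, band_id, fragment_size and at ",
         "least one genotype column", call. = FALSE)
  gen <- colnames(tab)[-(1:3)]
  cells <- as.matrix(tab[, -(1:3), drop = FALSE])
  ok <- matrix(cells %in% c("0", "1"), nrow = nrow(cells))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed cell '%s' at data row %d, genotype column '%s' (must be 0 or 1)",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 gen[bad[1L, 2L]]),
         call. = FALSE)
  }
  band_matrix(
    genotypes = gen,
    bands = data.frame(assay_id = tab[[1L]], band_id = tab[[2L]],
                       fragment_size = as.numeric(tab[[3L]])),
    presence = matrix(as.integer(cells), nrow = nrow(tab)),
    unit = unit
  )
}

#' Write a band matrix to tab-delimited text
#'
#' Emits the same dialect [read_band_matrix] accepts, deterministically:
#' tab-separated, bands sorted by assay then descending fragment size
#' (band_id breaks ties).
#'
#' @param x A [band_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path) {
  validate_band_matrix(x)
  o <- order(x$bands$assay_id, -x$bands$fragment_size, x$bands$band_id)
  out <- cbind(x$bands[o, c("assay_id", "band_id", "fragment_size")],
               as.data.frame(x$presence[o, , drop = FALSE]))
  colnames(out)[-(1:3)] <- x$genotypes
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a band's presence pattern
#'
#' Classes follow the standard dominant-marker accounting: a band is
#' *monomorphic* (MB) when present in every genotype; *unique positive* when
#' present in exactly one genotype; *unique negative* when absent from exactly
#' one; *absent* when amplified in none (legal only in synthetic data; never
#' scored); otherwise *polymorphic*. Unique bands of both kinds count toward
#' the polymorphic total (PB).
#'
#' @param presence Integer 0/1 vector over the genotype roster (length >= 2).
#' @return One of `"monomorphic"`, `"unique_pos"`, `"unique_neg"`,
#'   `"polymorphic_other"`, `"absent"`.
#' @export
#' @examples
#' classify_band(c(1, 1, 1, 1, 1, 1))  # monomorphic
#' classify_band(c(0, 0, 0, 1, 0, 0))  # unique_pos
classify_band <- function(presence) {
  n <- length(presence)
  if (n < 2L)
    stop("band classification needs at least two genotypes", call. = FALSE)
  if (!all(presence %in% c(0, 1)))
    stop("presence entries must be 0 or 1", call. = FALSE)
  s <- sum(presence)
  if (s == n) "monomorphic"
  else if (s == 0L) "absent"
  else if (s == 1L) "unique_pos"
  else if (s == n - 1L) "unique_neg"
  else "polymorphic_other"
}

#' @rdname classify_band
#' @param x A [band_matrix].
#' @return `band_classes()`: character vector of classes, one per band record.
#' @export
band_classes <- function(x) {
  apply(x$presence, 1L, classify_band)
}

#' Per-assay band accounting
#'
#' Counts band classes within one assay: monomorphic (MB), polymorphic (PB,
#' which includes the genotype-specific unique bands UB), and the total of
#' scored bands (TAB), so that MB + PB = TAB always holds. Bands present in
#' no genotype are never scored and are excluded from TAB. Fragment-size
#' bounds span the assay's scored bands.
#'
#' @param x A [band_matrix].
#' @param assay_id Assay to summarize; must exist in `x`.
#' @return One-row tibble with columns `assay_id`, `n_monomorphic`,
#'   `n_unique_pos`, `n_unique_neg`, `n_unique`, `n_polymorphic`, `n_total`,
#'   `fs_min`, `fs_max`.
#' @export
summarize_assay <- function(x, assay_id) {
  rows <- .assay_rows(x, assay_id)
  cls <- apply(x$presence[rows, , drop = FALSE], 1L, classify_band)
  scored <- cls != "absent"
  fs <- x$bands$fragment_size[rows][scored]
  mb <- sum(cls == "monomorphic")
  up <- sum(cls == "unique_pos")
  un <- sum(cls == "unique_neg")
  tab <- sum(scored)
  tibble::tibble(
    assay_id = assay_id,
    n_monomorphic = mb,
    n_unique_pos = up,
    n_unique_neg = un,
    n_unique = up + un,
    n_polymorphic = tab - mb,
    n_total = tab,
    fs_min = if (tab) min(fs) else NA_real_,
    fs_max = if (tab) max(fs) else NA_real_
  )
}

#' @rdname summarize_assay
#' @return `summarize_assays()`: tibble with one row per assay, in first
#'   appearance order.
#' @export
summarize_assays <- function(x) {
  do.call(rbind, lapply(assay_ids(x), function(a) summarize_assay(x, a)))
}

#' Catalogue genotype-specific (unique) bands per genotype
#'
#' For every genotype, counts the positive unique bands (bands only that
#' genotype carries) and negative unique bands (bands only that genotype
#' lacks). Summing both kinds over genotypes recovers the matrix-wide total
#' of genotype-specific markers.
#'
#' @param x A [band_matrix] with >= 2 genotypes.
#' @return Tibble with columns `genotype`, `n_pos`, `n_neg`, `n_specific`.
#' @export
unique_band_catalogue <- function(x) {
  if (length(x$genotypes) < 2L)
    stop("unique-band catalogue needs at least two genotypes", call. = FALSE)
  cls <- band_classes(x)
  npos <- nneg <- stats::setNames(integer(length(x$genotypes)), x$genotypes)
  for (i in seq_len(nrow(x$presence))) {
    if (cls[i] == "unique_pos") {
      g <- x$genotypes[which(x$presence[i, ] == 1L)]
      npos[g] <- npos[g] + 1L
    } else if (cls[i] == "unique_neg") {
      g <- x$genotypes[which(x$presence[i, ] == 0L)]
      nneg[g] <- nneg[g] + 1L
    }
  }
  tibble::tibble(genotype = x$genotypes, n_pos = unname(npos),
                 n_neg = unname(nneg), n_specific = unname(npos + nneg))
}

#' Restrict a band matrix to a subset of assays or genotypes
#'
#' @param x A [band_matrix].
#' @param assays Optional character vector of assay ids to keep.
#' @param genotypes Optional character vector of genotype labels to keep
#'   (order preserved as given).
#' @return A [band_matrix].
#' @export
subset_band_matrix <- function(x, assays = NULL, genotypes = NULL) {
  rows <- seq_len(nrow(x$bands))
  if (!is.null(assays)) {
    missing <- setdiff(assays, x$bands$assay_id)
    if (length(missing))
      stop("unknown assay_id: ", paste(missing, collapse = ", "),
           call. = FALSE)
    rows <- rows[x$bands$assay_id %in% assays]
  }
  cols <- x$genotypes
  if (!is.null(genotypes)) {
    missing <- setdiff(genotypes, x$genotypes)
    if (length(missing))
      stop("unknown genotype: ", paste(missing, collapse = ", "),
           call. = FALSE)
    cols <- genotypes
  }
  band_matrix(cols, x$bands[rows, , drop = FALSE],
              x$presence[rows, cols, drop = FALSE], unit = x$unit)
}
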