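#' Assemble a pipeline run configuration
#'
#' @param band_matrices Named list of band-matrix file paths, one per marker
#'   system (e.g. `list(ISSR = "issr.tsv", SCoT = "scot.tsv")`). Units are
#'   taken from `units` (default `"bp"`; use `"kDa"` for protein profiles).
#' @param karyotypes Optional path to a karyotype measurement table.
#' @param population_map Optional path to an individual-to-population map;
#'   when given, the band columns are treated as individuals for the
#'   population-genetics stage.
#' @param phenotypes Optional path to a phenotype table with columns
#'   `genotype,seed_yield,stover_yield` (harvest index is appended).
#' @param units Named character vector mapping marker-system name to size
#'   unit; systems not named default to `"bp"`.
#' @param pic_mode Assay-level PIC mode, see [informativeness_table()].
#' @param thresholds Arm-ratio classification bounds, see
#'   [classify_chromosomes()].
#' @param sd_type CV convention for karyotype summaries.
#' @param out_dir Output directory for report tables.
#' @param seed Integer seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters only when configs drive generators).
#' @param digits Display rounding for written report tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(band_matrices, karyotypes = NULL, population_map = NULL,
                       phenotypes = NULL, units = NULL,
                       pic_mode = "phenotype_freq",
                       thresholds = levan_thresholds, sd_type = "sample",
                       out_dir = "bandkaryo_out", seed = 1L, digits = 2) {
  stopifnot(length(band_matrices) >= 1L, digits >= 0)
  if (is.null(names(band_matrices)) || any(!nzchar(names(band_matrices))))
    stop("band_matrices must be a named list (one name per marker system)",
         call. = FALSE)
  structure(
    list(band_matrices = band_matrices, karyotypes = karyotypes,
         population_map = population_map, phenotypes = phenotypes,
         units = units, pic_mode = pic_mode, thresholds = thresholds,
         sd_type = sd_type, out_dir = out_dir, seed = as.integer(seed),
         digits = digits),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `band_matrices` is a mapping
#' of marker-system name to file path.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, c(
    list(band_matrices = y$band_matrices),
    y[setdiff(names(y), "band_matrices")]
  ))
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[bandkaryo] %-14s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full diversity analysis pipeline
#'
#' Executes band summarization, informativeness, the unique-band catalogue,
#' population genetics (when a population map is configured), karyotype
#' summaries (when measurements are configured), and Dice/UPGMA/PCoA
#' clustering per marker system and on the combined feature matrix. Every
#' table is written to the output directory and the run is recorded in a
#' JSON manifest (package version, config hash, seed), so identical configs
#' and inputs regenerate identical bundles. Every table value equals the
#' corresponding package function applied directly.
#'
#' @param config A [run_config] (or path to a YAML config).
#' @return Invisibly, a list (the report bundle): `informativeness` (named
#'   list of tibbles per marker system), `unique_bands`, `popgen`,
#'   `karyotype`, `similarity` (named list of matrices), `trees` (named list
#'   of `phylo`), `ordination`, `phenotypes`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dg <- config$digits

  mats <- .stage("read", {
    lapply(stats::setNames(nm = names(config$band_matrices)), function(sys) {
      unit <- if (!is.null(config$units) && sys %in% names(config$units))
        config$units[[sys]] else "bp"
      read_band_matrix(config$band_matrices[[sys]], unit = unit)
    })
  })

  info <- .stage("markers", {
    lapply(stats::setNames(nm = names(mats)), function(sys) {
      tbl <- informativeness_table(mats[[sys]], pic_mode = config$pic_mode)
      write_report_table(tbl, file.path(config$out_dir,
                                        paste0("informativeness_", sys, ".tsv")),
                         digits = dg)
      tbl
    })
  })

  uniq <- .stage("unique_bands", {
    tabs <- lapply(names(mats), function(sys) {
      u <- unique_band_catalogue(mats[[sys]])
      u$system <- sys
      u
    })
    out <- do.call(rbind, tabs)
    write_report_table(out, file.path(config$out_dir, "unique_bands.tsv"),
                       digits = dg)
    out
  })

  pg <- NULL
  if (!is.null(config$population_map)) {
    pg <- .stage("popgen", {
      pops <- read_population_map(config$population_map)
      tabs <- lapply(names(mats), function(sys) {
        s <- popgen_summary(mats[[sys]], pops)
        s$system <- sys
        s
      })
      out <- do.call(rbind, tabs)
      write_report_table(out, file.path(config$out_dir, "popgen.tsv"),
                         digits = 3)
      out
    })
  }

  karyo <- NULL
  if (!is.null(config$karyotypes)) {
    karyo <- .stage("karyotype", {
      sets <- read_karyotypes(config$karyotypes)
      out <- do.call(rbind, lapply(sets, karyotype_summary,
                                   sd_type = config$sd_type,
                                   thresholds = config$thresholds))
      write_report_table(out, file.path(config$out_dir, "karyotype.tsv"),
                         digits = dg)
      for (k in sets) {
        write_ideogram_svg(k, file.path(config$out_dir,
                                        paste0("ideogram_", k$genotype, ".svg")))
      }
      out
    })
  }

  clust <- .stage("cluster", {
    sims <- lapply(stats::setNames(nm = names(mats)),
                   function(sys) dice_matrix(mats[[sys]]))
    combined <- combined_feature_matrix(unname(mats), karyo)
    sims$combined <- dice_matrix(t(.binary_marker_part(combined)))
    trees <- lapply(sims, function(s) upgma(similarity_to_distance(s)))
    ords <- lapply(sims, function(s) pcoa(similarity_to_distance(s)))
    for (sys in names(sims)) {
      utils::write.table(round(sims[[sys]], 4),
                         file.path(config$out_dir,
                                   paste0("dice_", sys, ".tsv")),
                         sep = "\t", quote = FALSE)
      ape::write.tree(trees[[sys]],
                      file.path(config$out_dir,
                                paste0("upgma_", sys, ".nwk")))
      utils::write.table(round(ords[[sys]]$scores, 6),
                         file.path(config$out_dir,
                                   paste0("pcoa_", sys, ".tsv")),
                         sep = "\t", quote = FALSE)
    }
    utils::write.table(round(combined, 6),
                       file.path(config$out_dir, "combined_features.tsv"),
                       sep = "\t", quote = FALSE)
    list(similarity = sims, trees = trees, ordination = ords,
         combined = combined)
  })

  phen <- NULL
  if (!is.null(config$phenotypes)) {
    phen <- .stage("phenotypes", {
      tab <- utils::read.table(config$phenotypes, header = TRUE,
                               sep = if (grepl("\t", readLines(config$phenotypes,
                                                               n = 1L)))
                                 "\t" else ",")
      tab$harvest_index <- harvest_index(tab$seed_yield, tab$stover_yield)
      write_report_table(tab, file.path(config$out_dir, "phenotypes.tsv"),
                         digits = dg)
      tab
    })
  }

  manifest <- list(
    package = "bandkaryo",
    version = as.character(utils::packageVersion("bandkaryo")),
    seed = config$seed,
    config_hash = .config_hash(config),
    inputs = config$band_matrices,
    systems = names(mats),
    n_genotypes = length(mats[[1L]]$genotypes),
    n_bands = vapply(mats, n_bands, integer(1L))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(informativeness = info, unique_bands = uniq, popgen = pg,
                 karyotype = karyo, similarity = clust$similarity,
                 trees = clust$trees, ordination = clust$ordination,
                 combined = clust$combined, phenotypes = phen,
                 manifest = manifest))
}

# marker (binary) columns of a combined feature matrix
.binary_marker_part <- function(combined) {
  combined[, attr(combined, "provenance") == "marker", drop = FALSE]
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
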