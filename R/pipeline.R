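#' Default pipeline configuration
#'
#' All tunables of the atlas pipeline in one serialisable list: the
#' trimming profile and adapter, the organ map, classifier parameters and
#' the seed. `load_config()`/`save_config()` round-trip it through YAML.
#'
#' @param seed integer seed used for every stochastic stage of a run.
#' @param out_dir output directory for [run_atlas()].
#' @param ... overrides of individual defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "miratlas_out", ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    trimming_profile = "maastricht",
    organ_map = as.list(default_organ_map()),
    methods = c("rule", "nmf", "percentage", "demir"),
    expressed_threshold = 1,
    quorum_frac = 0.8,
    enriched_max_tissues = 5,
    percentage_specific = 90,
    percentage_enriched = 50,
    nmf_k = 14,
    nmf_dominance = 0.5,
    demir_alpha = 0.01,
    demir_d0 = 10,
    filter_threshold = 10,
    inputs = list(counts = NULL, reads = NULL, precursors = NULL,
                  annot = NULL)
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(
    cfg$quorum_frac > 0, cfg$quorum_frac <= 1,
    cfg$percentage_specific > cfg$percentage_enriched,
    cfg$percentage_enriched > 0, cfg$percentage_specific <= 100,
    cfg$demir_alpha > 0, cfg$demir_alpha < 1,
    cfg$demir_d0 >= 0, cfg$nmf_dominance > 0, cfg$nmf_dominance <= 1,
    cfg$enriched_max_tissues >= 2
  )
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$methods <- as.character(cfg$methods)
  # relative input paths are resolved against the config file's directory,
  # so a fixture bundle is relocatable
  base <- dirname(normalizePath(path))
  for (f in names(cfg$inputs)) {
    p <- cfg$inputs[[f]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) {
      cfg$inputs[[f]] <- file.path(base, p)
    }
  }
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write the demonstration fixture bundle
#'
#' Generates the default toy atlas used by the documentation and tests:
#' tiered precursors (FASTA + annotation TSV), simulated reads (FASTA), an
#' atlas count matrix with planted truth, and a qPCR study table, all from
#' one seed.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, named vector of the file paths written.
#' @export
make_demo_fixtures <- function(out_dir, seed = 101L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  paths <- c(
    precursors = file.path(out_dir, "precursors.fa"),
    annot = file.path(out_dir, "precursors_annot.tsv"),
    reads = file.path(out_dir, "reads.fa"),
    counts = file.path(out_dir, "atlas_counts.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    qpcr = file.path(out_dir, "qpcr_study.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  tiers <- generate_precursor_set(8L, c("rat", "mouse"), seed = seed)
  write_precursor_set(tiers$rat, paths[["precursors"]], paths[["annot"]])
  prof <- data.frame(offset5 = c(0L, 0L, 1L), offset3 = c(0L, 2L, 0L),
                     prob = c(0.6, 0.25, 0.15))
  reads <- generate_reads(tiers$rat, prof, n_reads = 400L, seed = seed + 1L)
  write_reads(reads$sequence, paths[["reads"]])

  tis <- names(default_organ_map())
  patterns <- c(
    list("liver", c("cerebrum", "cerebellum"), "heart"),
    rep(list(character(0)), 17)
  )
  design <- atlas_design(20L, enrichment_patterns = patterns,
                         lambda_high = 500, lambda_low = 1,
                         seed = seed + 2L)
  atl <- generate_atlas_counts(design)
  write_atlas_counts(atl$counts, paths[["counts"]])
  write_result_tsv(atl$truth, paths[["truth"]])

  lfc <- matrix(0, 3, 5)
  lfc[2, 3] <- 2; lfc[3, 3] <- 3; lfc[3, 4] <- 2
  qp <- generate_qpcr_study(true_log2fc = lfc, seed = seed + 3L)
  write_result_tsv(qp$wells, paths[["qpcr"]])

  # inputs as basenames (resolved by load_config) and a relative out_dir,
  # so two bundles from one seed are byte-identical wherever they live
  cfg <- pipeline_config(seed = seed, out_dir = ".")
  cfg$inputs <- lapply(
    paths[c("counts", "reads", "precursors", "annot")], basename)
  names(cfg$inputs) <- c("counts", "reads", "precursors", "annot")
  save_config(cfg, paths[["config"]])
  invisible(paths)
}

#' Run the atlas pipeline end to end
#'
#' Orchestrates read processing (when reads and precursors are configured),
#' quantification, every requested classifier, and the cross-method overlap
#' table. All outputs are TSV files under `cfg$out_dir`, plus a run log
#' naming the seed and the MD5 of the configuration so any stage can be
#' reproduced exactly.
#'
#' @param cfg a `pipeline_config` whose `inputs$counts` (and optionally
#'   `inputs$reads` / `inputs$precursors` / `inputs$annot`) point at
#'   existing files.
#' @return invisibly, a list with the calls per method, the venn table and
#'   the output paths.
#' @export
run_atlas <- function(cfg) {
  .validate_config(cfg)
  ins <- cfg$inputs
  if (is.null(ins$counts) || !file.exists(ins$counts)) {
    stop("input counts file missing: ", ins$counts %||% "<unset>",
         call. = FALSE)
  }
  for (f in c("reads", "precursors", "annot")) {
    if (!is.null(ins[[f]]) && !file.exists(ins[[f]])) {
      stop("configured input does not exist: ", ins[[f]], call. = FALSE)
    }
  }
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  organ_map <- unlist(cfg$organ_map)
  log_lines <- c(sprintf("seed\t%d", cfg$seed))
  warn_count <- 0L

  # --- read processing (optional stage) ---------------------------------
  if (!is.null(ins$reads) && !is.null(ins$precursors) && !is.null(ins$annot)) {
    raw <- read_reads(ins$reads)
    prof <- trimming_profile(cfg$trimming_profile)
    if (length(raw)) {
      tr <- trim_adapter(raw, cfg$adapter, min_len = prof$min_len,
                         max_len = prof$max_len,
                         match_prefix_len = prof$match_prefix_len,
                         drop_n = prof$drop_n,
                         keep_untrimmed = prof$keep_untrimmed)
      discards <- tr[!tr$keep, , drop = FALSE]
      collapsed <- collapse_reads(tr$insert[tr$keep], "DEM")
      ps <- read_precursor_set(ins$precursors, ins$annot)
      asg <- cross_species_assign(collapsed, list(rat = ps))
      divided <- divide_multilocus_counts(asg$assignments)
      write_result_tsv(divided, file.path(out_dir, "isomir_assignments.tsv"))
      write_result_tsv(discards, file.path(out_dir, "discard_report.tsv"))
      log_lines <- c(log_lines,
                     sprintf("reads_in\t%d", length(raw)),
                     sprintf("reads_discarded\t%d", nrow(discards)),
                     sprintf("sequences_unidentified\t%d",
                             nrow(asg$unidentified)))
    } else {
      warn_count <- warn_count + 1L
      log_lines <- c(log_lines, "warning\tempty read file; process stage skipped")
    }
  }

  # --- quantification ----------------------------------------------------
  atl <- read_atlas_counts(ins$counts)
  tm <- aggregate_tissue(atl)
  om <- aggregate_organ(tm, organ_map)
  write_result_tsv(data.frame(mirna = rownames(tm), tm,
                              check.names = FALSE),
                   file.path(out_dir, "tissue_counts.tsv"))
  write_result_tsv(data.frame(mirna = rownames(om), om,
                              check.names = FALSE),
                   file.path(out_dir, "organ_counts.tsv"))

  # --- classification ----------------------------------------------------
  calls <- list()
  if ("rule" %in% cfg$methods) {
    calls$rule <- classify_rule_based(
      atl, expressed_threshold = cfg$expressed_threshold,
      quorum_frac = cfg$quorum_frac,
      enriched_max_tissues = cfg$enriched_max_tissues
    )
  }
  if ("nmf" %in% cfg$methods) {
    nm <- classify_nmf_mixture(atl, k = min(cfg$nmf_k, ncol(om)),
                               seed = cfg$seed,
                               dominance = cfg$nmf_dominance,
                               organ_map = organ_map)
    calls$nmf <- nm$calls
  }
  if ("percentage" %in% cfg$methods) {
    calls$percentage <- classify_percentage(
      tm, specific_threshold = cfg$percentage_specific,
      enriched_threshold = cfg$percentage_enriched,
      organ_map = organ_map
    )
  }
  demir_res <- NULL
  if ("demir" %in% cfg$methods) {
    demir_res <- demir_one_vs_rest(atl, alpha = cfg$demir_alpha,
                                   d0 = cfg$demir_d0)
    write_result_tsv(demir_res, file.path(out_dir, "demir_results.tsv"))
    calls$demir <- data.frame(
      mirna = demir_enriched_set(demir_res),
      label = "enriched", tissues = "", organs = "", method = "demir",
      score = NA_real_, sex = NA_character_, stringsAsFactors = FALSE
    )
  }
  for (nm in names(calls)) {
    write_result_tsv(calls[[nm]],
                     file.path(out_dir, sprintf("calls_%s.tsv", nm)))
  }

  # --- cross-method comparison ------------------------------------------
  venn <- NULL
  sets <- lapply(calls, function(cl) {
    cl$mirna[cl$label %in% c("specific", "enriched")]
  })
  if (length(sets) >= 2L) {
    venn <- venn_compare(sets)
    write_result_tsv(venn, file.path(out_dir, "venn.tsv"))
  }

  # --- run log and summary ----------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.yaml")
  cfg_save <- cfg
  cfg_save$out_dir <- "."  # relative, so re-runs elsewhere are byte-identical
  save_config(cfg_save, cfg_path)
  log_lines <- c(log_lines,
                 sprintf("config_md5\t%s", unname(tools::md5sum(cfg_path))),
                 sprintf("warnings\t%d", warn_count),
                 vapply(names(calls), function(nm) {
                   sprintf("calls_%s\t%d", nm,
                           sum(calls[[nm]]$label != "none"))
                 }, character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  invisible(list(calls = calls, venn = venn, demir = demir_res,
                 out_dir = out_dir, warnings = warn_count))
}
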