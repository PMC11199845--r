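# species panel used by the fixture generator: 13 Sinocyclocheilus species
# with their eye morphs and body shapes; clade labels follow the
# B/C-mostly-stygomorphic, A/D-mostly-surface pattern and, where not
# individually published, are synthetic plausible assignments.
.species_panel <- data.frame(
  species = c("S_guilinensis", "S_zhenfengensis", "S_longibarbatus",
              "S_macrophthalmus", "S_oxycephalus", "S_purpureus",
              "S_maitianheensis", "S_mashanensis", "S_microphthalmus",
              "S_bicornutus", "S_multipunctatus", "S_tianlinensis",
              "S_tianeensis"),
  eye_morph = c("normal_eyed", "normal_eyed", "normal_eyed", "normal_eyed",
                "normal_eyed", "normal_eyed", "normal_eyed", "micro_eyed",
                "micro_eyed", "micro_eyed", "micro_eyed", "eyeless",
                "eyeless"),
  body_shape = c("compressiform", "compressiform", "compressiform",
                 "fusiform", "fusiform", "compressiform", "compressiform",
                 "compressiform", "compressiform", "compressiform",
                 "compressiform", "compressiform", "compressiform"),
  clade = c("A", "A", "D", "C", "D", "D", "D", "C", "B", "B", "C", "B", "B"),
  stringsAsFactors = FALSE)

# synthetic ultrametric 13-tip chronogram (root height 10 Myr) whose four
# subtrees carry the clade A-D labels above
.fixture_newick <- paste0(
  "((((S_tianlinensis:1.5,S_tianeensis:1.5):2.0,(S_microphthalmus:2.5,",
  "S_bicornutus:2.5):1.0):3.0,((S_macrophthalmus:2.0,S_mashanensis:2.0):2.0,",
  "S_multipunctatus:4.0):2.5):2.5,((S_guilinensis:3.0,S_zhenfengensis:3.0):4.0,",
  "((S_longibarbatus:2.0,S_oxycephalus:2.0):2.0,(S_purpureus:3.0,",
  "S_maitianheensis:3.0):1.0):3.0):2.0);")

#' Synthetic 13-species fixture chronogram
#'
#' A hand-written ultrametric tree over the 13-species panel, with a
#' clade map A-D; a synthetic stand-in for the study chronogram (the
#' published tree's branch lengths are not an input here).
#'
#' @return List: `tree` (a `phylo`), `clade_map` (named character vector
#'   species -> clade), `panel` (the species metadata data.frame).
#' @export
fixture_chronogram <- function() {
  tree <- read_newick(.fixture_newick)
  list(tree = tree,
       clade_map = stats::setNames(.species_panel$clade, .species_panel$species),
       panel = .species_panel)
}

#' Generate a self-consumable synthetic study folder
#'
#' Simulates `n_per_morph` trials per eye morph with the morph presets,
#' cycling over the species panel of each morph, and writes trajectory
#' CSVs, a metadata table, the fixture chronogram (Newick), a clade map
#' (YAML) and a study manifest (YAML) that [run_study()] accepts.
#'
#' @param n_per_morph Trials per eye morph (>= 1).
#' @param duration_s Trial duration (s), default 600.
#' @param seed Integer seed controlling all randomness.
#' @param outdir Output directory (created if needed).
#' @return The manifest as a list (invisibly also written to
#'   `manifest.yaml`).
#' @export
generate_fixture_study <- function(n_per_morph, duration_s = 600, seed = 1L,
                                   outdir) {
  stopifnot(n_per_morph >= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  arena <- arena_config()
  fx <- fixture_chronogram()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  meta <- list(); files <- character()
  trial_seed <- seed * 1000L
  for (morph in .eye_morphs) {
    pool <- .species_panel[.species_panel$eye_morph == morph, ]
    for (i in seq_len(n_per_morph)) {
      sp <- pool[((i - 1) %% nrow(pool)) + 1, ]
      id <- sprintf("%s_%02d", morph, i)
      sl <- round(stats::rnorm(1, 8.4, 1.28), 2)
      sl <- max(5, min(12, sl))
      ind <- individual_record(id, sp$species, morph, sl,
                               body_shape = sp$body_shape, clade = sp$clade)
      trial_seed <- trial_seed + 1L
      cfg <- morph_preset(morph, duration_s = duration_s, seed = trial_seed)
      tr <- simulate_trajectory(cfg, arena, ind)
      f <- file.path(outdir, paste0(id, ".csv"))
      write_trajectory_csv(tr, f)
      files <- c(files, basename(f))
      meta[[id]] <- data.frame(individual_id = id, species = sp$species,
                               eye_morph = morph, standard_length_cm = sl,
                               pectoral_fin_length_cm = round(sl * 0.22, 2),
                               body_shape = sp$body_shape, clade = sp$clade,
                               trajectory_file = basename(f),
                               stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, meta)
  utils::write.csv(md, file.path(outdir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  ape::write.tree(fx$tree, file.path(outdir, "chronogram_synthetic.nwk"))
  yaml::write_yaml(as.list(fx$clade_map), file.path(outdir, "clade_map.yaml"))
  manifest <- list(metadata = "metadata.csv",
                   trajectory_glob = "*.csv",
                   assay = "no_stimulation_10min",
                   testing_time_s = duration_s,
                   arena = list(width_cm = arena$width_cm,
                                height_cm = arena$height_cm),
                   tree = "chronogram_synthetic.nwk",
                   clade_map = "clade_map.yaml",
                   seed = seed)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  manifest$dir <- outdir
  invisible(manifest)
}

#' Read a study manifest
#' @param path Path to `manifest.yaml`.
#' @return Manifest list with `dir` set to the manifest's directory.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$dir <- dirname(normalizePath(path))
  m
}

#' Run the full wall-following analysis over a study folder
#'
#' For every individual in the manifest's metadata table: reads its
#' trajectory, repairs gaps, derives kinematics and computes the six
#' wall-following indicators (plus stimulation metrics and approaches
#' when the manifest configures a stimulus). Trials whose mobile time
#' falls below `min_mobile_frac` of the assay are dropped and logged.
#' Group statistics (Kruskal-Wallis across eye morphs, Dunnett T3, NB
#' regression with AICc full averaging of wall-following predictors) and
#' the phylogenetic stage (species means, Pagel's lambda per trait, clade
#' summaries) complete the report. Outputs are written as CSV/JSON and
#' are deterministic given the same inputs and seed.
#'
#' @param manifest Manifest list from [read_manifest()] or
#'   [generate_fixture_study()].
#' @param outdir Output directory for report files; default
#'   `file.path(manifest$dir, "results")`.
#' @param min_mobile_frac Minimum analysable mobile-time fraction,
#'   default 0.1.
#' @return List of class `study_result`: `metrics` (per-trial indicator
#'   table), `approaches`, `stats` (KW, pairwise, model averaging),
#'   `phylo` (species means, lambda table, clade summary), `dropped`
#'   (log of excluded trials), `files` (paths written).
#' @export
run_study <- function(manifest, outdir = NULL, min_mobile_frac = 0.1) {
  dir <- manifest$dir
  if (is.null(dir)) stop("manifest has no directory; read it with read_manifest()")
  if (is.null(outdir)) outdir <- file.path(dir, "results")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  arena <- arena_config(manifest$arena$width_cm, manifest$arena$height_cm)
  md <- read_metadata_table(file.path(dir, manifest$metadata))
  testing_time <- manifest$testing_time_s %||% assay_duration_s(manifest$assay)
  stim <- NULL
  if (!is.null(manifest$stimulus) && manifest$stimulus$kind != "none")
    stim <- stimulus_config(manifest$stimulus$kind, arena = arena)

  rows <- list(); approaches <- list(); dropped <- list()
  for (i in seq_len(nrow(md))) {
    rec <- md[i, ]
    f <- rec$trajectory_file
    if (is.null(f) || is.na(f)) f <- paste0(rec$individual_id, ".csv")
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("trajectory file not found for individual ",
                               rec$individual_id, ": ", fp)
    ind <- as_individual_record(rec)
    tr <- read_trajectory_csv(fp, arena, ind, assay = manifest$assay)
    tf <- fill_gaps(tr)
    k <- compute_kinematics(tf)
    mobile_s <- sum(.sample_dt(tf)[!k$resting_mask])
    if (mobile_s < min_mobile_frac * testing_time) {
      dropped[[length(dropped) + 1]] <- data.frame(
        individual_id = rec$individual_id, file = f,
        reason = sprintf("mobile time %.1f s below %.0f%% of assay",
                         mobile_s, 100 * min_mobile_frac))
      next
    }
    ev <- segment_wf_events(tf, k, arena, ind$standard_length_cm)
    m <- compute_wf_metrics(tf, k, ev, ind$standard_length_cm, testing_time)
    row <- cbind(data.frame(individual_id = ind$individual_id,
                            species = ind$species, eye_morph = ind$eye_morph,
                            clade = ind$clade, assay = manifest$assay,
                            standard_length_cm = ind$standard_length_cm,
                            stringsAsFactors = FALSE),
                 as.data.frame(m))
    if (!is.null(stim)) {
      sm <- compute_stimulation_metrics(tf, k, stim, ind$standard_length_cm,
                                        testing_time)
      row <- cbind(row, as.data.frame(sm))
      ap <- detect_approaches(tf, k, stim, ind$standard_length_cm)
      if (nrow(ap))
        approaches[[length(approaches) + 1]] <-
          cbind(individual_id = ind$individual_id, ap)
    }
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no analysable trials")
  metrics <- do.call(rbind, rows)
  approaches <- if (length(approaches)) do.call(rbind, approaches) else NULL
  dropped <- if (length(dropped)) do.call(rbind, dropped) else NULL

  # group statistics across eye morphs
  stats_report <- list()
  morph_groups <- split(metrics$wf_distance_sl, metrics$eye_morph)
  if (length(morph_groups) >= 2 && all(lengths(morph_groups) >= 2)) {
    stats_report$kruskal_wf_distance <- kruskal_wallis(morph_groups)
    stats_report$pairwise_wf_distance <- dunnett_t3(morph_groups)
    stats_report$group_means <- data.frame(
      eye_morph = names(morph_groups),
      n = lengths(morph_groups),
      mean = vapply(morph_groups, mean, 0),
      median = vapply(morph_groups, stats::median, 0),
      sd = vapply(morph_groups, stats::sd, 0),
      row.names = NULL)
  }
  pred_cols <- intersect(c("wf_frequency", "wf_time_pct", "wf_resting_time_s",
                           "wf_max_speed_sl_s", "standard_length_cm"),
                         names(metrics))
  usable <- vapply(metrics[pred_cols], function(v) stats::sd(v) > 0, TRUE)
  pred_cols <- pred_cols[usable]
  if (nrow(metrics) >= 15 && length(pred_cols) >= 2) {
    resp <- as.integer(round(metrics$wf_distance_sl))
    stats_report$model_average <- tryCatch(
      model_average_full(resp, metrics[pred_cols]),
      error = function(e) {
        warning("model averaging skipped: ", conditionMessage(e)); NULL
      })
  }

  # phylogenetic stage
  phylo_report <- list()
  if (!is.null(manifest$tree)) {
    tree <- read_newick(file.path(dir, manifest$tree))
    sp_means <- species_trait_table(metrics)
    shared <- intersect(tree$tip.label, sp_means$species)
    phylo_report$species_means <- sp_means
    if (length(shared) >= 4) {
      sub <- if (length(shared) < length(tree$tip.label))
        ape::drop.tip(tree, setdiff(tree$tip.label, shared)) else tree
      lam_rows <- list()
      for (tr_col in setdiff(names(sp_means), "species")) {
        v <- stats::setNames(sp_means[[tr_col]], sp_means$species)[shared]
        if (stats::var(v) == 0) next
        est <- estimate_lambda(sub, v)
        lam_rows[[tr_col]] <- data.frame(trait = tr_col,
                                         lambda_hat = est$lambda_hat,
                                         log_likelihood = est$log_likelihood,
                                         p_vs_zero = est$lrt_p_vs_zero)
      }
      phylo_report$lambda_table <- do.call(rbind, c(lam_rows,
                                                    make.row.names = FALSE))
    }
  }
  if (!all(is.na(metrics$clade)))
    phylo_report$clade_summary <- tryCatch(
      clade_summaries(metrics), warning = function(w) suppressWarnings(
        clade_summaries(metrics)))

  files <- character()
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  files <- c(files, wcsv(.round_df(metrics), "metrics.csv"))
  if (!is.null(approaches)) files <- c(files, wcsv(.round_df(approaches), "approaches.csv"))
  if (!is.null(dropped)) files <- c(files, wcsv(dropped, "dropped.csv"))
  rep <- list()
  if (!is.null(stats_report$kruskal_wf_distance))
    rep$kruskal_wf_distance <- unclass(stats_report$kruskal_wf_distance)
  if (!is.null(stats_report$pairwise_wf_distance))
    rep$pairwise_wf_distance <- stats_report$pairwise_wf_distance
  if (!is.null(stats_report$group_means)) rep$group_means <- stats_report$group_means
  if (!is.null(stats_report$model_average)) {
    rep$model_average_coefficients <- stats_report$model_average$averaged_coefficients
    rep$model_average_candidates <- stats_report$model_average$candidate_models
  }
  if (length(rep)) {
    p <- file.path(outdir, "stats_report.json")
    jsonlite::write_json(.json_ready(rep), p, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    files <- c(files, p)
  }
  if (length(phylo_report)) {
    p <- file.path(outdir, "phylo_report.json")
    jsonlite::write_json(.json_ready(phylo_report), p,
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    files <- c(files, p)
  }
  structure(list(metrics = metrics, approaches = approaches,
                 stats = stats_report, phylo = phylo_report,
                 dropped = dropped, files = files),
            class = "study_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip package S3 classes so jsonlite can serialise nested reports
.json_ready <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), .json_ready))
  x
}

# stable CSV formatting so identical analyses produce identical bytes
.round_df <- function(df, digits = 9) {
  for (j in names(df))
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d analysed trial(s), %d dropped\n",
              nrow(x$metrics), if (is.null(x$dropped)) 0 else nrow(x$dropped)))
  if (!is.null(x$stats$group_means)) print(x$stats$group_means, digits = 4)
  invisible(x)
}
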