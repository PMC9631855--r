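#' Configuration for a combining run
#'
#' Bundles everything [run_combine()] needs: the two rater files, the
#' combining parameters, the time dialect and tier layout, and output
#' options. The configuration is echoed verbatim into the JSON metrics
#' report and the discussion-list header, so published results always carry
#' the tolerance and correction they were produced under.
#'
#' @param rater1,rater2 paths to the two raters' ELAN tab-delimited exports.
#' @param tolerance_s tolerance in seconds (default 2).
#' @param correction `"exclude"` (default) or `"include"`.
#' @param dialect time dialect of the input files (see [parse_elan_time()]).
#' @param tier_map tier layout (see [read_elan_export()]).
#' @param trial_id trial identifier used in reports.
#' @param trial_duration_ms total observation duration; if `NULL`, the
#'   maximum end time over both raters is used.
#' @param out_dir output directory (created if missing).
#' @param metric_scope `"pre"` (default: agreement judged on the raters'
#'   initial overlap) or `"post"` (sensitivity variant judged after
#'   resolution: corrected gray time moves into the agreed cells and only
#'   discussion time remains as disagreement).
#' @param epoch_s optional epoch length in seconds for epoch-based metrics
#'   (see [tabulate_partition()]).
#' @param plot write a per-trial timeline figure (PDF) mirroring the
#'   black/white/gray bar layout.
#' @return a list of class `fog_run_config`.
#' @export
run_config <- function(rater1, rater2, tolerance_s = 2,
                       correction = c("exclude", "include"),
                       dialect = c("auto", "ms", "s.ms", "hh:mm:ss.ms"),
                       tier_map = list(fog = "FOG", trigger = NULL),
                       trial_id = "trial", trial_duration_ms = NULL,
                       out_dir = ".", metric_scope = c("pre", "post"),
                       epoch_s = NULL, plot = FALSE) {
  correction <- match.arg(correction)
  dialect <- match.arg(dialect)
  metric_scope <- match.arg(metric_scope)
  stopifnot(tolerance_s >= 0)
  structure(list(rater1 = rater1, rater2 = rater2,
                 tolerance_s = as.numeric(tolerance_s), correction = correction,
                 dialect = dialect, tier_map = tier_map, trial_id = trial_id,
                 trial_duration_ms = trial_duration_ms, out_dir = out_dir,
                 metric_scope = metric_scope,
                 epoch_s = if (is.null(epoch_s)) NULL else as.numeric(epoch_s),
                 plot = isTRUE(plot)),
            class = "fog_run_config")
}

post_resolution_table <- function(combined) {
  # sensitivity variant: corrected grays count as agreement, only
  # discussion time remains disagreement (split by annotating rater)
  res <- combined$resolved
  seg <- combined$partition$segments
  w <- res$end_ms - res$begin_ms
  disc <- res$outcome == "discussion"
  agreement_table(
    a_ms = sum(w[res$outcome == "FOG"]),
    b_ms = sum(seg$a_ms[disc]),
    c_ms = sum(seg$b_ms[disc]),
    d_ms = sum(w[res$outcome == "no_FOG"])
  )
}

#' Combine two annotation files and write all reports
#'
#' The end-to-end workflow for one trial: read both raters' ELAN exports,
#' combine them under the configured tolerance and correction, and write to
#' `out_dir`:
#'
#' * `combined.tsv` -- ELAN-reimportable resolved annotation table,
#' * `discussion.tsv` -- the to-be-discussed list for the third-rater session,
#' * `metrics.json` -- agreement metrics plus the verbatim configuration,
#' * `timeline.pdf` -- optional bar-layout figure of both raters, the
#'   partition and the resolved outcome.
#'
#' Every gray-segment resolution decision is logged (via `message()`) with
#' its provenance.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress decision logging.
#' @return the `fog_combined` object, invisibly, with an `artifacts`
#'   attribute listing the files written.
#' @export
run_combine <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "fog_run_config"))
  a <- read_elan_export(cfg$rater1, cfg$dialect, cfg$tier_map,
                        rater_id = "rater1", trial_id = cfg$trial_id)
  b <- read_elan_export(cfg$rater2, cfg$dialect, cfg$tier_map,
                        rater_id = "rater2", trial_id = cfg$trial_id)
  N <- cfg$trial_duration_ms
  if (is.null(N)) N <- max(a$trial_duration_ms, b$trial_duration_ms)
  a$trial_duration_ms <- N; b$trial_duration_ms <- N

  config <- combine_config(round(cfg$tolerance_s * 1000), cfg$correction)
  combined <- combine_tracks(a, b, config)

  if (!quiet) {
    res <- combined$resolved
    for (k in which(res$provenance %in%
                    c("gray-included", "gray-excluded→no_FOG",
                      "gray-isolated→discussion", "gray-long→discussion"))) {
      message(sprintf("[%s] gray [%d, %d) -> %s (%s)", cfg$trial_id,
                      res$begin_ms[k], res$end_ms[k], res$outcome[k],
                      res$provenance[k]))
    }
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(combined = file.path(cfg$out_dir, "combined.tsv"),
             discussion = file.path(cfg$out_dir, "discussion.tsv"),
             metrics = file.path(cfg$out_dir, "metrics.json"))
  write_resolved_table(combined, paths[["combined"]],
                       if (cfg$dialect == "auto") "hh:mm:ss.ms" else cfg$dialect)
  write_discussion_list(combined, paths[["discussion"]])

  tab <- if (cfg$metric_scope == "post") post_resolution_table(combined)
         else if (!is.null(cfg$epoch_s)) tabulate_partition(combined$partition, cfg$epoch_s * 1000)
         else combined$table
  report <- agreement_report(list(tab), cfg$trial_id)
  payload <- list(
    config = list(tolerance_s = cfg$tolerance_s, correction = cfg$correction,
                  dialect = cfg$dialect, metric_scope = cfg$metric_scope,
                  epoch_s = cfg$epoch_s, trial_duration_ms = N),
    table_ms = list(a = tab$a_ms, b = tab$b_ms, c = tab$c_ms, d = tab$d_ms),
    metrics = report,
    percent_time_frozen = percent_time_frozen(combined),
    n_discussion = sum(combined$resolved$outcome == "discussion")
  )
  jsonlite::write_json(payload, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  if (cfg$plot) {
    paths <- c(paths, timeline = file.path(cfg$out_dir, "timeline.pdf"))
    grDevices::pdf(paths[["timeline"]], width = 8, height = 3)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_timeline(combined, a, b)
  }
  attr(combined, "artifacts") <- paths
  invisible(combined)
}

#' Timeline bar plot of a combined trial
#'
#' Draws four horizontal bars: each rater's annotations, the black/gray
#' partition, and the resolved outcome (agreed FOG filled, discussion
#' hatched gray).
#'
#' @param combined a `fog_combined` object.
#' @param a,b the input [fog_track()]s.
#' @return invisibly `NULL`.
#' @export
plot_timeline <- function(combined, a, b) {
  N <- combined$partition$trial_duration_ms
  graphics::plot(NULL, xlim = c(0, N / 1000), ylim = c(0, 4.5), yaxt = "n",
                 xlab = "time (s)", ylab = "",
                 main = sprintf("trial '%s' (tolerance %g s, %s)",
                                combined$trial_id,
                                combined$config$tolerance_ms / 1000,
                                combined$config$correction))
  graphics::axis(2, at = c(0.5, 1.5, 2.5, 3.5) + 0.25,
                 labels = c("combined", "overlap", b$rater_id, a$rater_id),
                 las = 1, tick = FALSE)
  bar <- function(y, begin, end, col, border = "black") {
    if (length(begin)) {
      graphics::rect(begin / 1000, y, end / 1000, y + 0.5, col = col, border = border)
    }
  }
  bar(3.5, a$episodes$begin_ms, a$episodes$end_ms, "grey30")
  bar(2.5, b$episodes$begin_ms, b$episodes$end_ms, "grey30")
  seg <- combined$partition$segments
  cols <- c(black = "black", gray = "grey70", white = "white")
  bar(1.5, seg$begin_ms, seg$end_ms, cols[seg$color])
  res <- combined$resolved
  bar(0.5, res$begin_ms[res$outcome == "FOG"], res$end_ms[res$outcome == "FOG"], "black")
  bar(0.5, res$begin_ms[res$outcome == "discussion"],
      res$end_ms[res$outcome == "discussion"], "grey70", border = "red")
  invisible(NULL)
}

#' Generate a deterministic fixture set on disk
#'
#' Writes the ground-truth track and two simulated rater tracks as ELAN
#' tab-delimited exports, plus a JSON manifest recording the full simulation
#' spec (including the seed), to `out_dir`. Identical specs produce
#' byte-identical files.
#'
#' @param spec a [simulation_spec()], or a path to a JSON file with its
#'   fields.
#' @param out_dir output directory.
#' @param dialect time dialect for the written files.
#' @return named character vector of written paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir, dialect = c("hh:mm:ss.ms", "ms", "s.ms")) {
  dialect <- match.arg(dialect)
  if (is.character(spec)) {
    spec <- do.call(simulation_spec, jsonlite::read_json(spec, simplifyVector = TRUE))
  }
  stopifnot(inherits(spec, "fog_sim_spec"))
  truth <- generate_truth(spec)
  r1 <- simulate_rater(truth, spec, "rater1", 1L)
  r2 <- simulate_rater(truth, spec, "rater2", 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(truth = file.path(out_dir, "truth.tsv"),
             rater1 = file.path(out_dir, "rater1.tsv"),
             rater2 = file.path(out_dir, "rater2.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  for (nm in c("truth", "rater1", "rater2")) {
    tr <- switch(nm, truth = truth, rater1 = r1, rater2 = r2)
    write_track_elan(tr, paths[[nm]], dialect)
  }
  jsonlite::write_json(c(unclass(spec), list(dialect = dialect)),
                       paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Write a rater track as an ELAN tab-delimited export
#'
#' Episodes go on tier `"FOG"` with the phenotype as annotation value;
#' specified triggers go on a co-extensive `"FOG_trigger"` tier, matching
#' the layout [read_elan_export()] expects with
#' `tier_map = list(fog = "FOG", trigger = "FOG_trigger")`.
#'
#' @param track a [fog_track()].
#' @param path output file path.
#' @param dialect time dialect.
#' @return `path`, invisibly.
#' @export
write_track_elan <- function(track, path, dialect = c("hh:mm:ss.ms", "ms", "s.ms")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "fog_track"))
  eps <- track$episodes
  lines <- "Tier\tBegin Time\tEnd Time\tDuration\tAnnotation"
  for (k in seq_len(nrow(eps))) {
    lines <- c(lines, elan_row("FOG", eps$begin_ms[k], eps$end_ms[k],
                               eps$phenotype[k], dialect))
  }
  trg <- eps[eps$trigger != fog_unspecified, , drop = FALSE]
  for (k in seq_len(nrow(trg))) {
    lines <- c(lines, elan_row("FOG_trigger", trg$begin_ms[k], trg$end_ms[k],
                               trg$trigger[k], dialect))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Compute agreement metrics for a pair of annotation files
#'
#' Reads both raters' files, tabulates the duration-weighted 2x2 table from
#' their initial overlap and returns the per-trial [agreement_report()] row.
#'
#' @inheritParams run_config
#' @return a `data.frame`, see [agreement_report()].
#' @export
run_metrics <- function(rater1, rater2, dialect = "auto",
                        tier_map = list(fog = "FOG", trigger = NULL),
                        trial_id = "trial", trial_duration_ms = NULL,
                        epoch_s = NULL) {
  a <- read_elan_export(rater1, dialect, tier_map, "rater1", trial_id)
  b <- read_elan_export(rater2, dialect, tier_map, "rater2", trial_id)
  N <- trial_duration_ms
  if (is.null(N)) N <- max(a$trial_duration_ms, b$trial_duration_ms)
  a$trial_duration_ms <- N; b$trial_duration_ms <- N
  p <- partition_timeline(normalize_track(a), normalize_track(b))
  tab <- tabulate_partition(p, if (is.null(epoch_s)) NULL else epoch_s * 1000)
  agreement_report(list(tab), trial_id)
}
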