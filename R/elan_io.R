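#' Parse ELAN export time fields into integer milliseconds
#'
#' ELAN tab-delimited exports write times in one of three dialects:
#' `"ms"` (plain integer milliseconds), `"s.ms"` (decimal seconds, e.g.
#' `"2.500"`) or `"hh:mm:ss.ms"` (e.g. `"00:00:02.500"`). With
#' `dialect = "auto"` each field is sniffed independently: a field containing
#' `":"` is read as `hh:mm:ss.ms`, else one containing `"."` as `s.ms`, else
#' as `ms` (ambiguities are resolved in that order).
#'
#' @param x character vector of time fields.
#' @param dialect one of `"auto"`, `"ms"`, `"s.ms"`, `"hh:mm:ss.ms"`.
#' @return numeric vector of integer-valued milliseconds.
#' @export
parse_elan_time <- function(x, dialect = c("auto", "ms", "s.ms", "hh:mm:ss.ms")) {
  dialect <- match.arg(dialect)
  x <- trimws(as.character(x))
  one <- function(v) {
    d <- dialect
    if (d == "auto") {
      d <- if (grepl(":", v, fixed = TRUE)) "hh:mm:ss.ms"
           else if (grepl(".", v, fixed = TRUE)) "s.ms" else "ms"
    }
    out <- switch(d,
      "ms" = if (grepl("^[0-9]+$", v)) as.numeric(v) else NA_real_,
      "s.ms" = if (grepl("^[0-9]+(\\.[0-9]+)?$", v)) round(as.numeric(v) * 1000) else NA_real_,
      "hh:mm:ss.ms" = {
        if (!grepl("^[0-9]+:[0-5]?[0-9]:[0-5]?[0-9](\\.[0-9]+)?$", v)) NA_real_
        else {
          p <- strsplit(v, ":", fixed = TRUE)[[1L]]
          round((as.numeric(p[1L]) * 3600 + as.numeric(p[2L]) * 60 + as.numeric(p[3L])) * 1000)
        }
      })
    out
  }
  vapply(x, one, numeric(1), USE.NAMES = FALSE)
}

#' Format milliseconds in an ELAN export time dialect
#'
#' Inverse of [parse_elan_time()] at millisecond precision: for any integer
#' millisecond value, `parse_elan_time(format_elan_time(t, d), d)` returns `t`
#' exactly, in every dialect.
#'
#' @param ms numeric vector of integer milliseconds.
#' @param dialect one of `"ms"`, `"s.ms"`, `"hh:mm:ss.ms"`.
#' @return character vector.
#' @export
format_elan_time <- function(ms, dialect = c("ms", "s.ms", "hh:mm:ss.ms")) {
  dialect <- match.arg(dialect)
  ms <- round(as.numeric(ms))
  switch(dialect,
    "ms" = sprintf("%.0f", ms),
    "s.ms" = sprintf("%.3f", ms / 1000),
    "hh:mm:ss.ms" = {
      h <- ms %/% 3600000; r <- ms %% 3600000
      m <- r %/% 60000; r <- r %% 60000
      s <- r %/% 1000; f <- r %% 1000
      sprintf("%02.0f:%02.0f:%02.0f.%03.0f", h, m, s, f)
    })
}

split_annotation_value <- function(value) {
  # annotation values written by write_resolved_table carry flags appended
  # after ';' ("trembling;check_type"); the first token is the label proper
  parts <- strsplit(value, ";", fixed = TRUE)[[1L]]
  list(label = trimws(parts[1L]), flags = trimws(parts[-1L]))
}

parse_phenotype <- function(value) {
  lab <- tolower(split_annotation_value(value)$label)
  if (lab %in% fog_phenotypes) lab else fog_unspecified
}

read_elan_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read an ELAN tab-delimited annotation export
#'
#' Reads the tab-delimited export of an ELAN annotation tier set into a
#' [fog_track()]. The expected column layout is
#' `Tier <tab> Begin Time <tab> End Time <tab> [Duration <tab>] Annotation`
#' (the Duration column, present in some export configurations, is detected
#' by column count and ignored). A header row is detected by its time fields
#' failing to parse and is skipped, as are lines starting with `#`.
#'
#' `tier_map$fog` names the tier carrying FOG episodes: the annotation value
#' of each row on that tier is matched case-insensitively against
#' [fog_phenotypes] (anything else becomes `"unspecified"`).
#' `tier_map$trigger`, when non-`NULL`, names a second tier carrying trigger
#' annotations; a trigger is attached to an episode when the trigger
#' annotation overlaps more than half of the episode's duration (the
#' best-overlapping trigger wins when several qualify).
#'
#' @param path file path.
#' @param dialect time dialect, see [parse_elan_time()].
#' @param tier_map list with element `fog` (tier name, required) and
#'   optionally `trigger`.
#' @param rater_id,trial_id,trial_duration_ms passed to [fog_track()].
#' @param strict if `TRUE`, rows on tiers not named in `tier_map` are an
#'   error; by default they are ignored.
#' @return a [fog_track()] (not normalized; see [normalize_track()]).
#' @export
read_elan_export <- function(path, dialect = c("auto", "ms", "s.ms", "hh:mm:ss.ms"),
                             tier_map = list(fog = "FOG", trigger = NULL),
                             rater_id = "rater", trial_id = "trial",
                             trial_duration_ms = NULL, strict = FALSE) {
  dialect <- match.arg(dialect)
  if (is.null(tier_map$fog)) stop("tier_map$fog must name the FOG episode tier")
  rows <- read_elan_lines(path)
  if (length(rows) == 0L) {
    return(fog_track(NULL, rater_id, trial_id, trial_duration_ms))
  }
  ncol <- length(rows[[1L]])
  if (ncol < 4L) stop("expected at least 4 tab-delimited columns (Tier, Begin, End, Annotation)")
  ann_col <- if (ncol >= 5L) 5L else 4L
  # header row: its time fields do not parse as times
  first_times <- suppressWarnings(parse_elan_time(c(rows[[1L]][2L], rows[[1L]][3L]), dialect))
  if (any(is.na(first_times))) rows <- rows[-1L]

  tier <- character(0); begin <- numeric(0); end <- numeric(0); ann <- character(0)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < 4L) stop(sprintf("row %d: expected at least 4 columns, got %d", i, length(r)))
    t <- suppressWarnings(parse_elan_time(c(r[2L], r[3L]), dialect))
    if (any(is.na(t))) {
      stop(sprintf("row %d: cannot parse time field '%s' under dialect '%s'",
                   i, c(r[2L], r[3L])[which(is.na(t))[1L]], dialect))
    }
    if (t[1L] >= t[2L]) {
      stop(sprintf("row %d: begin time (%s) is not before end time (%s)", i, r[2L], r[3L]))
    }
    tier <- c(tier, r[1L]); begin <- c(begin, t[1L]); end <- c(end, t[2L])
    ann <- c(ann, if (length(r) >= ann_col) r[ann_col] else "")
  }

  known <- c(tier_map$fog, tier_map$trigger)
  if (strict && any(!tier %in% known)) {
    stop(sprintf("unknown tier '%s' (strict mode); expected one of: %s",
                 setdiff(tier, known)[1L], paste(known, collapse = ", ")))
  }

  is_fog <- tier == tier_map$fog
  eps <- new_episode_frame(begin[is_fog], end[is_fog],
                           vapply(ann[is_fog], parse_phenotype, character(1)),
                           rep(fog_unspecified, sum(is_fog)))
  if (!is.null(tier_map$trigger) && nrow(eps)) {
    is_trg <- tier == tier_map$trigger
    tb <- begin[is_trg]; te <- end[is_trg]; tv <- ann[is_trg]
    for (k in seq_len(nrow(eps))) {
      ov <- pmax(0, pmin(te, eps$end_ms[k]) - pmax(tb, eps$begin_ms[k]))
      dur <- eps$end_ms[k] - eps$begin_ms[k]
      if (length(ov) && max(ov) > dur / 2) {
        eps$trigger[k] <- split_annotation_value(tv[which.max(ov)])$label
      }
    }
  }
  fog_track(eps, rater_id, trial_id, trial_duration_ms)
}

elan_row <- function(tier, begin_ms, end_ms, value, dialect) {
  paste(tier, format_elan_time(begin_ms, dialect), format_elan_time(end_ms, dialect),
        format_elan_time(end_ms - begin_ms, dialect), value, sep = "\t")
}

#' Write combined annotations as an ELAN-reimportable tab-delimited table
#'
#' Writes the outcome of [combine_tracks()] (or a resolved-segment table from
#' [resolve_partition()]) as a tab-delimited file that ELAN can reimport:
#' one tier per outcome class. Agreed-FOG episodes go on tier `"FOG_agreed"`
#' with the phenotype as annotation value and any `check_type` /
#' `check_trigger` flags appended after `";"`; their triggers (when
#' specified) go on tier `"FOG_trigger"`; to-be-discussed segments go on tier
#' `"discussion"` with the reason as annotation value.
#'
#' Times are written at millisecond precision, so a
#' `read_elan_export(write_resolved_table(x))` round trip reproduces all
#' segment boundaries exactly in every dialect.
#'
#' @param x a `fog_combined` object from [combine_tracks()], or a resolved
#'   segment `data.frame` from [resolve_partition()].
#' @param path output file path.
#' @param dialect time dialect, see [format_elan_time()].
#' @return `path`, invisibly.
#' @export
write_resolved_table <- function(x, path, dialect = c("hh:mm:ss.ms", "ms", "s.ms")) {
  dialect <- match.arg(dialect)
  if (inherits(x, "fog_combined")) {
    episodes <- x$episodes
    resolved <- x$resolved
  } else {
    resolved <- x
    episodes <- merge_episodes(x)
  }
  lines <- "Tier\tBegin Time\tEnd Time\tDuration\tAnnotation"
  if (nrow(episodes)) {
    for (k in seq_len(nrow(episodes))) {
      flags <- c(if (isTRUE(episodes$check_type[k])) "check_type",
                 if (isTRUE(episodes$check_trigger[k])) "check_trigger")
      value <- paste(c(episodes$phenotype[k], flags), collapse = ";")
      lines <- c(lines, elan_row("FOG_agreed", episodes$begin_ms[k],
                                 episodes$end_ms[k], value, dialect))
    }
    trg <- episodes[episodes$trigger != fog_unspecified, , drop = FALSE]
    for (k in seq_len(nrow(trg))) {
      lines <- c(lines, elan_row("FOG_trigger", trg$begin_ms[k], trg$end_ms[k],
                                 trg$trigger[k], dialect))
    }
  }
  disc <- resolved[resolved$outcome == "discussion", , drop = FALSE]
  for (k in seq_len(nrow(disc))) {
    lines <- c(lines, elan_row("discussion", disc$begin_ms[k], disc$end_ms[k],
                               disc$provenance[k], dialect))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the discussion list for the third-rater session
#'
#' Plain-text tab-delimited report of every to-be-discussed segment: trial,
#' begin, end (seconds) and the reason it needs discussion (an isolated
#' possible FOG episode, or a non-isolated one longer than the tolerance).
#' The combining parameters are echoed in `#` header lines so the record of a
#' discussion session always carries the tolerance and correction it was
#' produced under.
#'
#' @param combined a `fog_combined` object from [combine_tracks()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_discussion_list <- function(combined, path) {
  stopifnot(inherits(combined, "fog_combined"))
  disc <- combined$resolved[combined$resolved$outcome == "discussion", , drop = FALSE]
  lines <- c(
    sprintf("# tolerance_ms: %s", format(combined$config$tolerance_ms)),
    sprintf("# correction: %s", combined$config$correction),
    "trial\tbegin_s\tend_s\treason"
  )
  for (k in seq_len(nrow(disc))) {
    lines <- c(lines, paste(combined$trial_id,
                            sprintf("%.3f", disc$begin_ms[k] / 1000),
                            sprintf("%.3f", disc$end_ms[k] / 1000),
                            disc$provenance[k], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
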