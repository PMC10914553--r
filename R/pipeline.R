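#' Run the respirometry analysis end-to-end
#'
#' For every fragment in the sample sheet: drawdown duration, the
#' VO2-versus-pO2 curve (blank- and volume-corrected), model selection
#' over the candidate family, and the regulation profile of the selected
#' model; then per-group means +/- SE and pairwise pooled t-tests per
#' statistic. Deterministic given its inputs. Fragments failing any stage
#' are flagged with the reason and excluded from summaries.
#'
#' @param config a list:
#' \describe{
#'   \item{sheet}{data frame with `chamber_id`, a grouping column
#'     (`group_col`, default "group"), and optionally more labels. All
#'     chamber_ids must resolve to traces.}
#'   \item{traces}{named list of `drawdown_trace` keyed by chamber_id, or
#'     `trace_dir` + optional `dialect` to read `<chamber_id>.csv` files.}
#'   \item{blanks}{named list keyed by chamber_id, a single
#'     `drawdown_trace` shared by all, or NULL.}
#'   \item{models}{candidate `model_spec` list (default
#'     [default_model_set()]).}
#'   \item{window, step, salinity, pressure}{passed to
#'     [compute_vo2_curve()].}
#'   \item{floor, grid_n, tpos_mode}{passed to [regulation_profile()].}
#'   \item{stats}{statistics to compare (default t_pos, p_cmax, p_cmin).}
#' }
#' @return list: `fragments` (per-fragment table), `groups` (mean/SE per
#'   group and statistic), `comparisons` (pairwise t-tests), `fits`
#'   (per-fragment ranked fit tables), `flagged` (reasons, if any).
#' @export
run_hrc_pipeline <- function(config) {
  sheet <- config$sheet
  if (is.null(sheet) || nrow(sheet) == 0L) {
    stop("run_hrc_pipeline: empty sample sheet", call. = FALSE)
  }
  group_col <- config$group_col %||% "group"
  stopifnot(all(c("chamber_id", group_col) %in% names(sheet)))
  traces <- config$traces
  if (is.null(traces)) {
    if (is.null(config$trace_dir)) {
      stop("run_hrc_pipeline: need traces or trace_dir", call. = FALSE)
    }
    traces <- lapply(stats::setNames(nm = sheet$chamber_id), function(id) {
      read_firesting_csv(file.path(config$trace_dir, paste0(id, ".csv")),
                         meta = as.list(sheet[sheet$chamber_id == id, ]),
                         dialect = config$dialect %||%
                           list(time = "time_s", o2 = "airsat_pct",
                                temperature = "temp_C"))
    })
  }
  missing_ids <- setdiff(sheet$chamber_id, names(traces))
  if (length(missing_ids)) {
    stop("run_hrc_pipeline: no trace for chamber_id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  blank_for <- function(id) {
    b <- config$blanks
    if (is.null(b)) return(NULL)
    if (inherits(b, "drawdown_trace")) return(b)
    b[[id]]
  }
  models <- config$models %||% default_model_set()
  stats_ <- config$stats %||% c("t_pos", "p_cmax", "p_cmin")

  rows <- list()
  fits <- list()
  flagged <- character(0)
  for (i in seq_len(nrow(sheet))) {
    id <- sheet$chamber_id[i]
    res <- tryCatch({
      tr <- traces[[id]]
      dur <- drawdown_duration(tr)
      rates <- compute_vo2_curve(tr, blank_for(id),
                                 window = config$window %||% 600,
                                 step = config$step %||% 300,
                                 salinity = config$salinity %||% 35,
                                 pressure = config$pressure %||% 1013.25)
      curve <- normalize_curve(rates)
      sel <- select_best(curve, models)
      prof <- regulation_profile(sel$best,
                                 grid_n = config$grid_n %||% 1000,
                                 floor = config$floor %||% 0.02,
                                 tpos_mode = config$tpos_mode %||% "integral")
      fits[[id]] <- sel$table
      data.frame(chamber_id = id, group = sheet[[group_col]][i],
                 duration_h = dur$hours, censored = dur$censored,
                 best_model = format(sel$best$spec),
                 rss = sel$best$rss, aic = sel$best$aic,
                 t_pos = prof$t_pos, t_neg = prof$t_neg,
                 p_cmax = prof$p_cmax, p_cmin = prof$p_cmin,
                 flagged = FALSE, flag_reason = "")
    }, error = function(e) {
      data.frame(chamber_id = id, group = sheet[[group_col]][i],
                 duration_h = NA_real_, censored = NA,
                 best_model = NA_character_, rss = NA_real_, aic = NA_real_,
                 t_pos = NA_real_, t_neg = NA_real_, p_cmax = NA_real_,
                 p_cmin = NA_real_, flagged = TRUE,
                 flag_reason = conditionMessage(e))
    })
    rows[[i]] <- res
    if (res$flagged) flagged[id] <- res$flag_reason
  }
  fragments <- do.call(rbind, rows)
  ok <- fragments[!fragments$flagged, , drop = FALSE]

  groups <- do.call(rbind, lapply(split(ok, ok$group), function(gdf) {
    do.call(rbind, lapply(c("duration_h", stats_), function(s) {
      v <- gdf[[s]][is.finite(gdf[[s]])]
      data.frame(group = gdf$group[1], statistic = s,
                 mean = if (length(v)) mean(v) else NA_real_,
                 se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                      else NA_real_,
                 n = length(v))
    }))
  }))
  rownames(groups) <- NULL

  comparisons <- list()
  gl <- unique(ok$group)
  if (length(gl) >= 2L) {
    pairs <- utils::combn(gl, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(c("duration_h", stats_), function(s) {
        va <- ok[[s]][ok$group == pr[1] & is.finite(ok[[s]])]
        vb <- ok[[s]][ok$group == pr[2] & is.finite(ok[[s]])]
        if (length(va) < 2L || length(vb) < 2L) return(NULL)
        ct <- two_sample_t(va, vb, method = config$t_method %||% "pooled")
        data.frame(statistic = s, group_a = pr[1], group_b = pr[2],
                   t = ct$statistic, df = ct$df, p = ct$p,
                   mean_a = unname(ct$estimate_a["mean"]),
                   mean_b = unname(ct$estimate_b["mean"]))
      }))
    }))
    rownames(comparisons) <- NULL
  }
  list(fragments = fragments, groups = groups, comparisons = comparisons,
       fits = fits, flagged = flagged)
}

#' Read a sample sheet from CSV or YAML
#'
#' The sheet keys chamber metadata by `chamber_id`. YAML sheets are a list
#' of records; both forms are returned as a data frame.
#'
#' @param path `.csv`, `.yaml` or `.yml` file.
#' @return data frame with one row per chamber.
#' @export
read_sample_sheet <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  } else {
    df <- utils::read.csv(path)
  }
  if (!"chamber_id" %in% names(df)) {
    stop("read_sample_sheet: sheet must have a chamber_id column",
         call. = FALSE)
  }
  df
}

#' Field logger summaries and the cross-colony delta correlation
#'
#' Per colony: interior and exterior deployment summaries, cumulative
#' time-at-DO histograms and interior-versus-exterior deltas; then across
#' colonies, the Pearson correlations of delta-mean-DO versus delta-T_pos
#' and delta-range-DO versus delta-T_pos, where delta-T_pos = interior
#' minus exterior colony-level mean T_pos and the DO deltas are exterior
#' minus interior (from [interior_exterior_delta()]).
#'
#' @param config a list:
#' \describe{
#'   \item{field}{named list, one entry per colony: `list(interior =,
#'     exterior =)` `field_series`.}
#'   \item{fragments}{per-fragment table from [run_hrc_pipeline()] whose
#'     sheet carried `colony` and `position` columns (copied into the
#'     fragments table via the group label "colony.position", or supply a
#'     data frame with `colony`, `position`, `t_pos`).}
#'   \item{thresholds, bin_width}{passed to the summaries.}
#' }
#' @return list: `colonies` (per-colony summaries, histograms, deltas),
#'   `correlation_mean`, `correlation_range` (each a `group_comparison`
#'   or an error message when degenerate), `small_n` flag (TRUE when
#'   fewer than 3 colonies).
#' @export
run_field_pipeline <- function(config) {
  field <- config$field
  if (is.null(field) || length(field) < 2L) {
    stop("run_field_pipeline: need >= 2 colonies with field series",
         call. = FALSE)
  }
  frag <- config$fragments
  stopifnot(all(c("colony", "position", "t_pos") %in% names(frag)))
  colonies <- lapply(stats::setNames(nm = names(field)), function(cn) {
    pair <- field[[cn]]
    list(
      summary_interior = summarize_series(pair$interior,
                                          config$thresholds %||% c(2, 5)),
      summary_exterior = summarize_series(pair$exterior,
                                          config$thresholds %||% c(2, 5)),
      hist_interior = cumulative_time_histogram(pair$interior,
                                                config$bin_width %||% 0.5),
      hist_exterior = cumulative_time_histogram(pair$exterior,
                                                config$bin_width %||% 0.5),
      delta = interior_exterior_delta(pair$interior, pair$exterior),
      d_tpos = {
        fi <- frag$t_pos[frag$colony == cn & frag$position == "interior"]
        fe <- frag$t_pos[frag$colony == cn & frag$position == "exterior"]
        mean(fi[is.finite(fi)]) - mean(fe[is.finite(fe)])
      })
  })
  d_tpos <- vapply(colonies, `[[`, 0, "d_tpos")
  d_mean <- vapply(colonies, function(cc) cc$delta$delta_mean, 0)
  d_range <- vapply(colonies, function(cc) cc$delta$delta_range, 0)
  corr <- function(x, y) {
    tryCatch(pearson(x, y), error = function(e) conditionMessage(e))
  }
  list(colonies = colonies,
       correlation_mean = corr(d_mean, d_tpos),
       correlation_range = corr(d_range, d_tpos),
       small_n = length(field) < 3L)
}
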