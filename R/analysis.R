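# Ensemble post-processing: adiabatic population curves, internal-coordinate
# time series, photorelaxation-channel classification and fraction
# summaries.

.non_excluded <- function(ensemble) {
  Filter(function(tr) !tr$failed, ensemble$trajectories)
}

#' Adiabatic population curves of an ensemble
#'
#' At each time point, the fraction of non-excluded trajectories whose
#' active state carries each label.  Terminated trajectories are counted
#' according to the protocol's assumptions: after internal conversion the
#' trajectory is counted in S0 for the remaining time; after
#' triplet-trapping it is counted in T1; a timed-out trajectory keeps its
#' final state.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param times Time grid (fs); defaults to the recording grid up to the
#'   configured maximum time.
#' @return A data.frame with `time_fs` and one column per state label;
#'   rows sum to one.
#' @export
adiabatic_populations <- function(ensemble, times = NULL) {
  trajs <- .non_excluded(ensemble)
  if (!length(trajs)) stop("no non-excluded trajectories in the ensemble")
  cfg <- ensemble$config
  if (is.null(times))
    times <- seq(0, cfg$t_max, by = cfg$dt * cfg$record_every)
  labels <- sort(unique(unlist(lapply(trajs, function(tr) tr$label))))
  labels <- union(labels, c("S0", "T1"))
  labels <- labels[order(substr(labels, 1, 1),
                         as.integer(substring(labels, 2)))]
  P <- matrix(0, length(times), length(labels),
              dimnames = list(NULL, labels))
  for (tr in trajs) {
    after <- switch(tr$termination$reason,
                    internal_conversion = "S0",
                    triplet_trapped = "T1",
                    tr$label[length(tr$label)])
    idx <- findInterval(times, tr$times)
    lab <- ifelse(idx < 1, tr$label[1],
                  ifelse(times > tr$termination$time, after,
                         tr$label[pmax(idx, 1)]))
    for (l in unique(lab)) P[lab == l, l] <- P[lab == l, l] + 1
  }
  P <- P / length(trajs)
  data.frame(time_fs = times, P, check.names = FALSE)
}

#' Internal-coordinate time series of a trajectory
#'
#' Tilt-angle coordinates are reported as absolute values.
#'
#' @param trajectory An `sh_trajectory`.
#' @param coordinates Coordinate names (default: all recorded).
#' @return A data.frame with `time_fs` and one column per coordinate.
#' @export
internal_coordinates <- function(trajectory,
                                 coordinates = colnames(trajectory$positions)) {
  avail <- colnames(trajectory$positions)
  bad <- setdiff(coordinates, avail)
  if (length(bad))
    stop("unknown coordinate(s) ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  out <- data.frame(time_fs = trajectory$times)
  for (cn in coordinates) {
    v <- trajectory$positions[, cn]
    if (grepl("theta|angle|tilt", cn)) v <- abs(v)
    out[[cn]] <- v
  }
  out
}

#' Classify the photorelaxation channel of a terminated trajectory
#'
#' Precedence: C-O dissociation, then N-H dissociation, then the residual
#' gap-closure branch.  A trajectory that terminated through the
#' ground-state-gap criterion with the C(2)-O bond beyond the dissociation
#' threshold is ring opening; beyond the N-H threshold it is N-H fission;
#' with all bonds intact it is the photostabilising channel (C-S tilting
#' and ring puckering).  Timed-out trajectories are `other`.  The
#' `CO5-opening` label is reserved for models carrying a second ring-bond
#' coordinate; the shipped surrogate does not emit it.  Failed
#' trajectories are `excluded` and never classified.
#'
#' @param trajectory An `sh_trajectory`.
#' @param thresholds Named dissociation thresholds in Angstrom
#'   (defaults: `r_CO = 1.8`, `r_NH = 1.8`).
#' @return List with `channel` and `manifold`.
#' @export
classify_channel <- function(trajectory,
                             thresholds = c(r_CO = 1.8, r_NH = 1.8)) {
  if (trajectory$failed)
    return(list(channel = "excluded", manifold = NA_character_))
  last <- nrow(trajectory$positions)
  manifold <- trajectory$termination$manifold
  if (trajectory$termination$reason == "timeout")
    return(list(channel = "other", manifold = manifold))
  rco <- trajectory$positions[last, "r_CO"]
  rnh <- if ("r_NH" %in% colnames(trajectory$positions))
    trajectory$positions[last, "r_NH"] else -Inf
  channel <- if (!is.na(rco) && rco > thresholds[["r_CO"]]) "ring-opening-CO"
  else if (!is.na(rnh) && rnh > thresholds[["r_NH"]]) "NH-fission"
  else "photostabilising"
  list(channel = channel, manifold = manifold)
}

.CHANNELS <- c("ring-opening-CO", "NH-fission", "photostabilising",
               "CO5-opening", "other")

#' Summarize photorelaxation channels of an ensemble
#'
#' Counts and fractions per channel over the non-excluded trajectories
#' (fractions as exact rationals and rounded to the nearest percent, the
#' convention used when reporting ensembles of this size), the
#' singlet/triplet split per channel, the excluded-trajectory count and
#' the initial-state counts.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param thresholds Passed to [classify_channel()].
#' @return A `channel_summary` list.
#' @export
summarize_ensemble <- function(ensemble,
                               thresholds = c(r_CO = 1.8, r_NH = 1.8)) {
  trajs <- ensemble$trajectories
  cls <- lapply(trajs, classify_channel, thresholds = thresholds)
  ch <- vapply(cls, function(x) x$channel, "")
  mf <- vapply(cls, function(x) x$manifold, "")
  keep <- ch != "excluded"
  n <- sum(keep)
  if (n == 0) stop("all trajectories are excluded")
  counts <- vapply(.CHANNELS, function(x) sum(ch[keep] == x), 0L)
  manifold_split <- t(vapply(.CHANNELS, function(x)
    c(singlet = sum(ch[keep] == x & mf[keep] == "singlet"),
      triplet = sum(ch[keep] == x & mf[keep] == "triplet")),
    c(singlet = 0, triplet = 0)))
  init <- table(vapply(trajs[keep], function(tr) tr$label[1], ""))
  structure(list(
    n = n,
    excluded = sum(!keep),
    counts = counts,
    fractions = counts / n,
    percents = round(100 * counts / n),
    manifold_split = manifold_split,
    manifold_totals = c(singlet = sum(mf[keep] == "singlet"),
                        triplet = sum(mf[keep] == "triplet")),
    initial_state_counts = init,
    initial_state_percents = initial_state_percentages(init),
    thresholds = thresholds
  ), class = "channel_summary")
}

#' @export
print.channel_summary <- function(x, ...) {
  cat("channel_summary over", x$n, "trajectories (",
      x$excluded, "excluded )\n")
  df <- data.frame(count = x$counts, percent = x$percents,
                   singlet = x$manifold_split[, "singlet"],
                   triplet = x$manifold_split[, "triplet"])
  print(df)
  cat("manifold totals:",
      paste(names(x$manifold_totals), x$manifold_totals, collapse = ", "),
      "\n")
  invisible(x)
}

#' Initial-state percentages, rounded to the nearest percent
#'
#' @param counts Named integer vector (or table) of per-state counts.
#' @return Named numeric vector of percentages rounded to the nearest
#'   percent; the exact fractions are attached as attribute `"exact"`.
#' @examples
#' initial_state_percentages(c(S2 = 120, S3 = 16, S1 = 5))  # 85, 11, 4
#' @export
initial_state_percentages <- function(counts) {
  counts <- unclass(counts)
  tot <- sum(counts)
  if (tot <= 0) stop("counts must sum to a positive total")
  pct <- round(100 * counts / tot)
  attr(pct, "exact") <- counts / tot
  pct
}

#' Write a channel summary as JSON
#'
#' @param summary A [summarize_ensemble()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_channel_summary <- function(summary, path) {
  out <- list(
    n = summary$n, excluded = summary$excluded,
    channels = lapply(seq_along(summary$counts), function(i) list(
      channel = names(summary$counts)[i],
      count = unname(summary$counts[i]),
      fraction = unname(summary$fractions[i]),
      percent = unname(summary$percents[i]),
      singlet = unname(summary$manifold_split[i, "singlet"]),
      triplet = unname(summary$manifold_split[i, "triplet"]))),
    manifold_totals = as.list(summary$manifold_totals),
    initial_state_counts = as.list(unclass(summary$initial_state_counts)),
    thresholds = as.list(summary$thresholds))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
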