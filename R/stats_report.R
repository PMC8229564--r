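#' Paired two-tailed Student's t test
#'
#' Closed-form paired test on the elementwise differences `a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample SD (n - 1 denominator)
#' and a two-tailed p value from the t distribution with `n - 1` degrees of
#' freedom. If every difference is zero the statistic is undefined and a
#' degenerate result is flagged.
#'
#' @param a,b numeric vectors of equal length, n >= 2
#' @return object of class `paired_t`: list with `n`, `mean_diff`, `t_stat`,
#'   `df`, `p_two_tailed`, `degenerate`, and per-vector `(mean, sem)` in
#'   `mean_sem_a`, `mean_sem_b`
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  degenerate <- s == 0 && md == 0
  if (degenerate) {
    t_stat <- NA_real_; p <- NA_real_
  } else if (s == 0) {
    t_stat <- sign(md) * Inf; p <- 0
  } else {
    t_stat <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  structure(list(n = n, mean_diff = md, t_stat = t_stat, df = n - 1,
                 p_two_tailed = p, degenerate = degenerate,
                 mean_sem_a = c(mean = mean(a), sem = sd(a) / sqrt(n)),
                 mean_sem_b = c(mean = mean(b), sem = sd(b) / sqrt(n))),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired t test: degenerate (all differences zero), n = %d\n",
                x$n))
  } else {
    cat(sprintf(
      "paired t test: t = %.4f, df = %d, p = %.3g, mean diff = %.4f (n = %d)\n",
      x$t_stat, x$df, x$p_two_tailed, x$mean_diff, x$n))
  }
  invisible(x)
}

#' Summarise vascular vs avascular faces over polarity records
#'
#' Drops records with any missing face value (listwise), then reports per
#' face and channel the mean with both SEM and SD, and paired two-tailed t
#' tests comparing the vascular with the avascular face for laminin and for
#' insulin.
#'
#' @param records data.frame of polarity records from [analyse_islet()]
#' @param json optional path; the report is additionally written as JSON
#' @return object of class `face_report`
#' @export
summarize_faces <- function(records, json = NULL) {
  need <- c("laminin_vascular", "laminin_avascular",
            "insulin_vascular", "insulin_avascular")
  complete <- records[stats::complete.cases(records[, need]), , drop = FALSE]
  if (nrow(complete) < 2) stop("need at least 2 complete records")
  msd <- function(x) list(mean = mean(x), sd = sd(x),
                          sem = sd(x) / sqrt(length(x)))
  rep <- list(
    n_records = nrow(records),
    n_complete = nrow(complete),
    n_dropped = nrow(records) - nrow(complete),
    laminin = list(vascular = msd(complete$laminin_vascular),
                   avascular = msd(complete$laminin_avascular)),
    insulin = list(vascular = msd(complete$insulin_vascular),
                   avascular = msd(complete$insulin_avascular)),
    laminin_test = paired_t_test(complete$laminin_vascular,
                                 complete$laminin_avascular),
    insulin_test = paired_t_test(complete$insulin_vascular,
                                 complete$insulin_avascular))
  if (!is.null(json)) {
    j <- rep
    j$laminin_test <- unclass(j$laminin_test)
    j$insulin_test <- unclass(j$insulin_test)
    jsonlite::write_json(j, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  structure(rep, class = "face_report")
}

#' @export
print.face_report <- function(x, ...) {
  fmt <- function(ch, f) sprintf("%7.2f +/- %.2f (SEM; SD %.2f)",
                                 x[[ch]][[f]]$mean, x[[ch]][[f]]$sem,
                                 x[[ch]][[f]]$sd)
  cat(sprintf("face report over %d complete cell records (%d dropped)\n",
              x$n_complete, x$n_dropped))
  cat("  laminin  vascular ", fmt("laminin", "vascular"), "\n")
  cat("  laminin avascular ", fmt("laminin", "avascular"), "\n")
  cat("  insulin  vascular ", fmt("insulin", "vascular"), "\n")
  cat("  insulin avascular ", fmt("insulin", "avascular"), "\n")
  cat("  laminin: "); print(x$laminin_test)
  cat("  insulin: "); print(x$insulin_test)
  invisible(x)
}

#' Render an intensity heat map over cells or boundaries
#'
#' Maps the channel intensities of in-cell (or boundary) pixels through a
#' blue-to-red lookup table; background pixels show the optional grey-scale
#' overlay (for example laminin) or black.
#'
#' @param channel intensity matrix
#' @param lm instance label map
#' @param mode colour whole cells or only their boundary pixels
#' @param background optional matrix shown as grey scale outside the
#'   coloured pixels
#' @return H x W x 3 RGB array in [0, 1]
#' @export
render_heatmap <- function(channel, lm, mode = c("cells", "boundaries"),
                           background = NULL) {
  mode <- match.arg(mode)
  channel <- unclass(channel)
  stopifnot(all(dim(channel) == dim(lm)))
  sel <- if (mode == "cells") lm > 0 else extract_boundaries(lm) == 1
  h <- nrow(channel); w <- ncol(channel)
  out <- array(0, c(h, w, 3))
  if (!is.null(background)) {
    bg <- pmin(pmax(unclass(background) / 255, 0), 1)
    for (k in 1:3) out[, , k] <- bg
  }
  if (any(sel)) {
    v <- channel[sel]
    t <- if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else
      rep(0.5, length(v))
    R <- out[, , 1]; G <- out[, , 2]; B <- out[, , 3]
    R[sel] <- pmax(0, 2 * t - 1)
    G[sel] <- 1 - abs(2 * t - 1)
    B[sel] <- pmax(0, 1 - 2 * t)
    out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
  }
  out
}
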