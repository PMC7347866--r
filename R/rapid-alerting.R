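#' Configuration for the surprise-index pipeline
#'
#' Collects the tunable parameters of the full per-minute pipeline:
#' validity filtering, windowing, singular-vector conditioning, VAR order,
#' dissimilarity, projection training, index composition and alerting.
#'
#' @param validity A [validity_config()].
#' @param window_len,stride Scoring window length and stride (minutes).
#' @param locf_limit Maximum gap carried forward inside a window (minutes).
#' @param completeness_floor Minimum observed fraction for a usable window.
#' @param svd_rank Retained rank of the signal conditioning.
#' @param var_order VAR order of the per-window dynamics models.
#' @param dissim_kind `"symkl"` or `"coeff_frobenius"`.
#' @param n_reference_windows Shared reference windows for the symmetrised
#'   KL dissimilarity.
#' @param ns_centres,ns_max_iter,ns_tol Projection-training controls.
#' @param percentile Alarm-calibration percentile of the training index.
#' @param density_weight Weight of the novelty (negative log training
#'   density) component added to the magnification component; 0 disables it.
#' @param warmup First scored minute (earlier minutes use no index).
#' @param impute_limit Longest sensor gap imputed from the phenotype space
#'   (minutes).
#' @param k_range Candidate phenotype counts.
#' @param max_models,model_stride Training-model budget and window stride.
#' @param min_training_duration Minimum training-session duration (minutes).
#' @param calibration_split Fraction of the eligible training sessions held
#'   out from map-building and used only to calibrate the alarm threshold,
#'   so the threshold reflects the index distribution of patients the map
#'   has not seen (0 calibrates in-sample).
#' @param calibration_minutes Per-minute index budget pooled for threshold
#'   calibration.
#' @return A list of class `rapid_config`.
#' @export
rapid_config <- function(validity = validity_config(),
                         window_len = 15, stride = 1,
                         locf_limit = 5, completeness_floor = 0.8,
                         svd_rank = 2, var_order = 2,
                         dissim_kind = "symkl", n_reference_windows = 8,
                         ns_centres = 50, ns_max_iter = 400, ns_tol = 1e-6,
                         percentile = 95, density_weight = 1,
                         warmup = 5, impute_limit = 15,
                         k_range = 2:8,
                         max_models = 100, model_stride = 30,
                         min_training_duration = 240,
                         calibration_split = 0.3,
                         calibration_minutes = 20000) {
  structure(as.list(environment()), class = "rapid_config")
}

# 2-D kernel density of the training projections (product Gaussian kernel).
kde_density <- function(Y, y, bw) {
  z1 <- (y[1] - Y[, 1]) / bw[1]
  z2 <- (y[2] - Y[, 2]) / bw[2]
  mean(exp(-0.5 * (z1^2 + z2^2))) / (2 * pi * bw[1] * bw[2])
}

robust_stats <- function(x) {
  x <- x[is.finite(x)]
  med <- stats::median(x)
  s <- stats::mad(x)
  if (!is.finite(s) || s == 0) s <- max(stats::sd(x), 1e-6)
  if (!is.finite(s) || s == 0) s <- 1e-6
  list(med = med, scale = s)
}

#' Train the full patient-adaptive surprise-index model
#'
#' From a set of stable training sessions: computes frozen channel
#' statistics, fits per-window VAR dynamics models, builds their
#' symmetrised-KL dissimilarity matrix, trains the topographic projection,
#' standardizes the log-magnification and novelty components against the
#' training distribution, clusters the training projections into patient
#' phenotypes, and calibrates the alarm threshold as an empirical
#' percentile of the pooled per-minute training index.
#'
#' Sessions with deterioration annotations or shorter than
#' `min_training_duration` are excluded from training.
#'
#' @param sessions List of [monitoring_session()] objects (filtered or not).
#' @param config A [rapid_config()].
#' @param seed Integer seed controlling subsampling, basis selection and
#'   clustering.
#' @return An object of class `rapid_model`.
#' @export
train_rapid_model <- function(sessions, config = rapid_config(), seed = 1) {
  sessions <- lapply(sessions, function(s)
    if (is.null(s$validity)) filter_session(s, config$validity) else s)
  keep <- vapply(sessions, function(s) {
    is.null(s$annotations) &&
      (s$intended_end - s$intended_start) > config$min_training_duration
  }, logical(1))
  sessions <- sessions[keep]
  if (length(sessions) < 2)
    stopf("need at least 2 eligible training sessions (stable, > %d min)",
          config$min_training_duration)

  # hold out part of the cohort for out-of-sample threshold calibration
  n_cal <- min(length(sessions) - 2,
               round(config$calibration_split * length(sessions)))
  cal_sessions <- sessions
  if (n_cal >= 1) {
    cal_idx <- with_seed(seed + 1, sample.int(length(sessions), n_cal))
    cal_sessions <- sessions[cal_idx]
    sessions <- sessions[-cal_idx]
  }

  cs <- channel_stats(sessions)

  models <- list()
  features <- list()
  winstats <- list()
  for (s in sessions) {
    wins <- make_windows(s, config$window_len, stride = config$model_stride,
                         locf_limit = config$locf_limit,
                         completeness_floor = config$completeness_floor)
    for (w in wins) {
      if (!w$usable) next
      fv <- svd_condition(standardize_window(w, cs), config$svd_rank)
      m <- fit_var(fv, config$var_order, warn = FALSE)
      models[[length(models) + 1L]] <- m
      features[[length(features) + 1L]] <- fv
      winstats[[length(winstats) + 1L]] <- c(
        colMeans(w$values),
        apply(w$values, 2, stats::sd),
        apply(w$values, 2, function(x) {
          a <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
          if (is.finite(a)) a else 0
        }))
    }
  }
  if (length(models) < 4)
    stopf("too few usable training windows (%d)", length(models))

  with_seed(seed, {
    if (length(models) > config$max_models) {
      pick <- sort(sample.int(length(models), config$max_models))
      models <- models[pick]
      features <- features[pick]
      winstats <- winstats[pick]
    }
    refs <- features[sample.int(length(features),
                                min(config$n_reference_windows, length(features)))]
  })

  D <- build_dissimilarity_matrix(models, refs, kind = config$dissim_kind)
  desc <- t(vapply(models, model_descriptor,
                   numeric(length(model_descriptor(models[[1]])))))
  map <- train_neuroscale(desc, D, n_centres = config$ns_centres,
                          max_iter = config$ns_max_iter, tol = config$ns_tol,
                          seed = seed)

  logmag <- vapply(seq_len(nrow(desc)), function(i)
    log(max(local_metric(map, desc[i, ])$magnification, 1e-12)), numeric(1))
  mag_stats <- robust_stats(logmag)

  bw <- apply(map$Y, 2, stats::bw.nrd0)
  bw[!is.finite(bw) | bw <= 0] <- 0.1
  novelty <- vapply(seq_len(nrow(map$Y)), function(i)
    -log(max(kde_density(map$Y, map$Y[i, ], bw), 1e-300)), numeric(1))
  den_stats <- robust_stats(novelty)

  ws <- do.call(rbind, winstats)
  phen <- fit_phenotypes(map$Y, k_range = config$k_range, seed = seed,
                         channel_data = ws)

  model <- structure(list(map = map, channel_stats = cs, config = config,
                          mag_stats = mag_stats, den_stats = den_stats,
                          bw = bw, phenotypes = phen,
                          ref_windows = refs,
                          threshold = NA_real_, calibration = NULL,
                          seed = seed),
                     class = "rapid_model")

  # calibrate on the deployed statistic: the pooled per-minute index of the
  # held-out calibration sessions
  vals <- numeric(0)
  for (s in cal_sessions) {
    idx <- compute_rapid_index(s, model)
    vals <- c(vals, idx$data$index[!is.na(idx$data$index)])
    if (length(vals) >= config$calibration_minutes) break
  }
  model$threshold <- calibrate_threshold(vals, config$percentile)
  model$calibration <- list(n_sessions = length(cal_sessions),
                            n_minutes = length(vals),
                            median = stats::median(vals),
                            percentile = config$percentile)
  model
}

#' @export
print.rapid_model <- function(x, ...) {
  cat(sprintf("<rapid_model> %d training models, %d phenotypes, stress %.4g\n",
              x$map$n_train, x$phenotypes$k, x$map$stress))
  cat(sprintf("  threshold %.3f (percentile %g over %d calibration minutes)\n",
              x$threshold, x$config$percentile, x$calibration$n_minutes))
  invisible(x)
}

#' Compute the per-minute surprise index for a session
#'
#' For every minute from the warm-up onward, the window ending at that
#' minute is standardized, conditioned, modelled, flattened to a
#' descriptor, projected through the trained map, and scored as the sum of
#' two floored robust z-scores against the training distribution: the
#' log-magnification of the map at the projection and (optionally,
#' weighted) the negative log training density there. Sensor gaps of at
#' most `impute_limit` minutes are filled from the patient's current
#' phenotype AR model conditioned on the last observed value (carry-forward
#' before a phenotype is assigned); longer gaps leave the index
#' unavailable.
#'
#' @param session A [monitoring_session()] (filtered on the fly if needed).
#' @param model A trained `rapid_model`.
#' @return Object of class `rapid_index_series`: `session_id`, `threshold`
#'   and a data frame `data` with columns `minute`, `index`, `flag`
#'   (`warmup`/`direct`/`imputed`/`unavailable`).
#' @export
compute_rapid_index <- function(session, model) {
  cfg <- model$config
  if (is.null(session$validity))
    session <- filter_session(session, cfg$validity)
  grid <- session_grid(session)
  T_int <- nrow(grid)
  cs <- model$channel_stats
  phen <- model$phenotypes
  wlen <- cfg$window_len
  warmup <- cfg$warmup

  filled <- grid
  imputed <- matrix(FALSE, T_int, 3)
  gap <- c(0L, 0L, 0L)
  last <- rep(NA_real_, 3)
  cur_phen <- NA_integer_

  index <- rep(NA_real_, T_int)
  flag <- rep("warmup", T_int)

  Wmu <- cs$mean[CHANNELS]
  Wsd <- cs$sd[CHANNELS]
  mag_med <- model$mag_stats$med; mag_sc <- model$mag_stats$scale
  den_med <- model$den_stats$med; den_sc <- model$den_stats$scale
  w_den <- cfg$density_weight

  for (t in seq_len(T_int)) {
    for (ch in 1:3) {
      v <- grid[t, ch]
      if (!is.na(v)) {
        gap[ch] <- 0L
        last[ch] <- v
      } else {
        gap[ch] <- gap[ch] + 1L
        if (!is.na(last[ch]) && gap[ch] <= cfg$impute_limit) {
          if (!is.na(cur_phen) && !is.null(phen$channel_stats)) {
            ps <- phen$channel_stats[[cur_phen]]
            filled[t, ch] <- ps$mean[ch] +
              ps$phi[ch]^gap[ch] * (last[ch] - ps$mean[ch])
          } else {
            filled[t, ch] <- last[ch]
          }
          imputed[t, ch] <- TRUE
        } else {
          filled[t, ch] <- NA_real_
        }
      }
    }
    tm <- t - 1L  # 0-based minute
    if (tm < warmup) next
    s0 <- max(1L, t - wlen + 1L)
    vals <- filled[s0:t, , drop = FALSE]
    if (anyNA(vals)) {
      flag[t] <- "unavailable"
      next
    }
    std <- sweep(sweep(vals, 2, Wmu), 2, Wsd, "/")
    fv <- svd_condition(window_from_values(std, session$session_id, s0 - 1L),
                        cfg$svd_rank)
    dm <- fit_var(fv, cfg$var_order, warn = FALSE)
    d <- model_descriptor(dm)
    y <- as.numeric(predict(model$map, d))
    lm <- local_metric(model$map, d)
    # two-sided: both stretching (sparse regions) and collapse (far from the
    # training support, where the RBF Jacobian decays) signal novelty
    val <- abs(log(max(lm$magnification, 1e-300)) - mag_med) / mag_sc
    if (w_den > 0) {
      nov <- -log(max(kde_density(model$map$Y, y, model$bw), 1e-300))
      val <- val + w_den * max((nov - den_med) / den_sc, 0)
    }
    index[t] <- val
    flag[t] <- if (any(imputed[s0:t, ])) "imputed" else "direct"
    if (!is.null(phen$centroids)) {
      d2 <- rowSums(sweep(phen$centroids, 2, y)^2)
      cur_phen <- which.min(d2)
    }
  }

  structure(list(session_id = session$session_id,
                 threshold = model$threshold,
                 data = data.frame(minute = seq_len(T_int) - 1L +
                                     session$intended_start,
                                   index = index, flag = flag,
                                   stringsAsFactors = FALSE)),
            class = "rapid_index_series")
}

#' @export
print.rapid_index_series <- function(x, ...) {
  ok <- !is.na(x$data$index)
  cat(sprintf("<rapid_index_series '%s'> %d minutes, %d scored, median %.3f, threshold %.3f\n",
              x$session_id, nrow(x$data), sum(ok),
              stats::median(x$data$index[ok]), x$threshold))
  invisible(x)
}

#' Calibrate the alarm threshold
#'
#' Empirical nearest-rank percentile of the training index values.
#'
#' @param values Numeric vector of at least 100 index values.
#' @param percentile Percentile in (0, 100].
#' @return The threshold.
#' @export
calibrate_threshold <- function(values, percentile = 95) {
  values <- values[is.finite(values)]
  if (length(values) < 100)
    stopf("need at least 100 index values to calibrate (got %d)",
          length(values))
  nearest_rank(values, percentile)
}

#' Extract alarm events from an index series
#'
#' Maximal contiguous runs of minutes with index at or above the threshold.
#'
#' @param series A `rapid_index_series` (or data frame with `minute` and
#'   `index`).
#' @param threshold Alarm threshold; defaults to the series' own.
#' @param min_duration Minimum run length in minutes to report.
#' @return Data frame `session_id, start_minute, end_minute, peak_index`.
#' @export
generate_alerts <- function(series, threshold = NULL, min_duration = 1) {
  if (inherits(series, "rapid_index_series")) {
    df <- series$data
    sid <- series$session_id
    if (is.null(threshold)) threshold <- series$threshold
  } else {
    df <- series
    sid <- df$session_id[1] %||% "session"
  }
  if (is.null(threshold) || is.na(threshold))
    stopf("an alarm threshold is required")
  if (nrow(df) == 0) stopf("empty index series")
  above <- !is.na(df$index) & df$index >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  out <- data.frame(session_id = character(0), start_minute = numeric(0),
                    end_minute = numeric(0), peak_index = numeric(0),
                    stringsAsFactors = FALSE)
  if (any(keep)) {
    out <- data.frame(
      session_id = sid,
      start_minute = df$minute[starts[keep]],
      end_minute = df$minute[ends[keep]],
      peak_index = vapply(which(keep), function(i)
        max(df$index[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out
}

#' Cluster training projections into patient phenotypes
#'
#' k-means over the 2-D training projections with the cluster count chosen
#' by the best average silhouette width over `k_range`. Each phenotype
#' carries representative channel statistics (mean, sd and lag-1
#' autocorrelation per channel) pooled from its member windows, which
#' drive short-gap imputation.
#'
#' @param projections `n x 2` matrix of training projections.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @param channel_data Optional `n x 9` matrix (per-window channel means,
#'   sds and lag-1 autocorrelations, in that column order).
#' @return Object of class `phenotype_model`.
#' @export
fit_phenotypes <- function(projections, k_range = 2:10, seed = 1,
                           channel_data = NULL) {
  Y <- as.matrix(projections)
  n <- nrow(Y)
  spread <- max(stats::dist(Y))
  if (!is.finite(spread) || spread < 1e-10) {
    warnf("all projections identical; using a single phenotype")
    assign <- rep(1L, n)
    centroids <- Y[1, , drop = FALSE]
    k <- 1L
    sil <- NA_real_
  } else {
    k_range <- k_range[k_range >= 2 & k_range < n]
    if (!length(k_range)) k_range <- 2
    dY <- stats::dist(Y)
    fits <- with_seed(seed, lapply(k_range, function(k)
      stats::kmeans(Y, k, nstart = 10, iter.max = 50)))
    sils <- vapply(seq_along(k_range), function(i) {
      cl <- fits[[i]]$cluster
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, dY)[, "sil_width"])
    }, numeric(1))
    best <- which.max(sils)
    k <- k_range[best]
    sil <- sils[best]
    assign <- fits[[best]]$cluster
    centroids <- fits[[best]]$centers
  }
  chstats <- NULL
  if (!is.null(channel_data)) {
    chstats <- lapply(seq_len(k), function(cl) {
      sub <- channel_data[assign == cl, , drop = FALSE]
      m <- colMeans(sub)
      list(mean = m[1:3], sd = pmax(m[4:6], 0), phi = pmin(pmax(m[7:9], 0), 0.999))
    })
  }
  structure(list(centroids = centroids, assignment = assign, k = k,
                 silhouette = sil, channel_stats = chstats,
                 k_range = k_range, seed = seed),
            class = "phenotype_model")
}

#' Impute short sensor gaps from the phenotype space
#'
#' Fills per-channel gaps of at most `limit` minutes with the conditional
#' mean path of the assigned phenotype's AR(1) model,
#' `mean + phi^k (last_observed - mean)`; longer gaps are refused and left
#' missing. With no phenotype assigned the last observation is carried
#' forward instead.
#'
#' @param session A filtered [monitoring_session()].
#' @param phenotype A `phenotype_model`.
#' @param phenotype_id Cluster index of the patient's current phenotype,
#'   or `NA` for carry-forward only.
#' @param limit Longest gap imputed, minutes.
#' @return List with `values` (T x 3 matrix, imputed cells filled) and
#'   `imputed` (logical matrix of the same shape).
#' @export
impute_missing <- function(session, phenotype, phenotype_id = NA,
                           limit = 15) {
  if (is.null(session$validity))
    stopf("session must be filtered before imputation")
  grid <- session_grid(session)
  imputed <- matrix(FALSE, nrow(grid), 3,
                    dimnames = dimnames(grid))
  ps <- if (!is.na(phenotype_id) && !is.null(phenotype$channel_stats))
    phenotype$channel_stats[[phenotype_id]] else NULL
  for (ch in 1:3) {
    x <- grid[, ch]
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      # refuse gaps longer than the limit, and leading gaps (nothing observed)
      if (!r$values[i] || r$lengths[i] > limit || starts[i] == 1L) next
      last <- x[starts[i] - 1L]
      ks <- seq_len(r$lengths[i])
      idx <- starts[i]:ends[i]
      grid[idx, ch] <- if (!is.null(ps))
        ps$mean[ch] + ps$phi[ch]^ks * (last - ps$mean[ch]) else last
      imputed[idx, ch] <- TRUE
    }
  }
  list(values = grid, imputed = imputed)
}
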