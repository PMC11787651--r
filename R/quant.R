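# Quantification engine: isotope-cluster XIC extraction from MS1, peak
# detection/integration, retention-time-driven identity assignment, and
# linear-equation splitting of co-eluting isobaric positional isomers
# using discriminating fragment-ion signals.

.default_quant_config <- function() {
  list(ppm_ms1 = 10, ppm_ms2 = 20, rt_tolerance_min = 0.5,
       n_isotopes = 3L, noise_floor = 0, min_points = 6L,
       split_method = "spans", calibrate = TRUE, window_match_tol = 0.01)
}

# per-spectrum level/window lookup, computed once per run and cached
.spec_meta <- function(run) {
  meta <- attr(run, "spec_meta")
  if (!is.null(meta)) return(meta)
  list(lev = vapply(run$spectra, `[[`, numeric(1), "ms_level"),
       wl = vapply(run$spectra, function(s)
         if (is.null(s$window_low)) NA_real_ else s$window_low, numeric(1)),
       wh = vapply(run$spectra, function(s)
         if (is.null(s$window_high)) NA_real_ else s$window_high,
         numeric(1)))
}

#' Cache per-spectrum metadata on a run
#'
#' Precomputes the level/window lookup used by [extract_xic()]; worthwhile
#' before repeated extractions from the same run.
#' @param run a \code{dia_run}.
#' @return the run with the lookup attached.
#' @export
index_run <- function(run) {
  attr(run, "spec_meta") <- .spec_meta(run)
  attr(run, "windows") <- run_windows(run)
  run
}

# index spectra of a run by level (and window for MS2)
.run_index <- function(run, ms_level, window = NULL, tol = 0.01) {
  meta <- .spec_meta(run)
  sel <- meta$lev == ms_level
  if (ms_level == 2) {
    if (is.null(window)) stop("MS2 extraction requires a window")
    sel <- sel & !is.na(meta$wl) & abs(meta$wl - window[1]) <= tol &
      abs(meta$wh - window[2]) <= tol
    if (!any(sel)) stop("isolation window (", window[1], ", ", window[2],
                        ") not found in run")
  }
  which(sel)
}

#' Extract an ion chromatogram
#'
#' Per-spectrum sum of centroided intensities within \code{ppm} of a
#' target m/z, at MS1 or within one DIA window at MS2.
#'
#' @param run a \code{dia_run}.
#' @param mz target m/z (vector allowed; one trace per target).
#' @param ppm mass tolerance in ppm (10 for MS1, 20 for MS2 by default
#'   downstream).
#' @param ms_level 1 or 2.
#' @param window numeric(2) (low, high) isolation window, required at
#'   MS2; matched against the run's windows within 0.01 m/z.
#' @param rt_range optional numeric(2) restricting the trace (minutes).
#' @return for scalar \code{mz} an \code{xic_trace} data.frame(rt,
#'   intensity); otherwise a list of traces.
#' @export
extract_xic <- function(run, mz, ppm, ms_level = 1L, window = NULL,
                        rt_range = NULL) {
  idx <- .run_index(run, ms_level, window)
  rts <- vapply(run$spectra[idx], `[[`, numeric(1), "rt")
  if (!is.null(rt_range)) {
    keep <- rts >= rt_range[1] & rts <= rt_range[2]
    idx <- idx[keep]; rts <- rts[keep]
  }
  lo <- mz * (1 - ppm * 1e-6)
  hi <- mz * (1 + ppm * 1e-6)
  mat <- matrix(0, nrow = length(idx), ncol = length(mz))
  for (r in seq_along(idx)) {
    s <- run$spectra[[idx[r]]]
    if (!length(s$mz)) next
    cs <- c(0, cumsum(s$intensity))
    i0 <- findInterval(lo, s$mz) # last peak strictly below lo
    i1 <- findInterval(hi, s$mz) # last peak <= hi
    mat[r, ] <- cs[i1 + 1] - cs[i0 + 1]
  }
  mk <- function(j) structure(data.frame(rt = rts, intensity = mat[, j]),
                              class = c("xic_trace", "data.frame"),
                              mz = mz[j], ppm = ppm)
  if (length(mz) == 1L) mk(1L) else lapply(seq_along(mz), mk)
}

# 3-point moving average, ends kept
.smooth3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  s <- y
  s[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  s
}

#' Detect and integrate a chromatographic peak
#'
#' Applies 3-point moving-average smoothing, picks the maximal smoothed
#' local apex within \code{expected_rt +/- rt_tolerance} (tie broken
#' toward the expected RT), and extends the integration boundaries
#' outward to the first sample below 1\% of the apex (on the raw trace)
#' or a smoothed local valley. The area is the trapezoidal integral of
#' the raw trace (intensity x minutes) over the boundaries; the points
#' across the peak count the samples at or above the 1\% threshold.
#' Returns NULL when no apex clears the noise floor,
#' \code{max(abs_floor, 3 * median(trace))}.
#'
#' @param trace an \code{xic_trace}.
#' @param expected_rt expected apex retention time (minutes).
#' @param rt_tolerance half-width of the assignment window (minutes).
#' @param abs_floor configured absolute noise floor.
#' @return a \code{chrom_peak} list (rt_apex, height, left, right, area,
#'   points, indices) or NULL.
#' @export
detect_peak <- function(trace, expected_rt, rt_tolerance = 0.5,
                        abs_floor = 0) {
  y <- trace$intensity
  rt <- trace$rt
  n <- length(y)
  if (!n || all(y <= 0)) return(NULL)
  s <- .smooth3(y)
  floor_ <- max(abs_floor, 3 * stats::median(y))
  in_win <- which(abs(rt - expected_rt) <= rt_tolerance)
  if (!length(in_win)) return(NULL)
  is_max <- vapply(in_win, function(i) {
    l <- if (i > 1) s[i - 1] else -Inf
    r <- if (i < n) s[i + 1] else -Inf
    s[i] >= l && s[i] >= r && s[i] > 0
  }, logical(1))
  cand <- in_win[is_max]
  if (!length(cand)) return(NULL)
  best <- max(s[cand])
  cand <- cand[s[cand] >= best * (1 - 1e-12)]
  apex <- cand[which.min(abs(rt[cand] - expected_rt))]
  if (s[apex] < floor_) return(NULL)
  thr <- 0.01 * y[apex] # 1% of apex, on the raw trace
  left <- apex
  while (left > 1) {
    if (y[left - 1] < thr) { left <- left - 1; break } # first sample < 1%
    if (s[left - 1] > s[left]) break                   # local valley
    left <- left - 1
  }
  right <- apex
  while (right < n) {
    if (y[right + 1] < thr) { right <- right + 1; break }
    if (s[right + 1] > s[right]) break
    right <- right + 1
  }
  ii <- left:right
  area <- if (length(ii) > 1)
    sum((y[ii[-length(ii)]] + y[ii[-1]]) / 2 * diff(rt[ii])) else 0
  structure(list(rt_apex = rt[apex], height = max(y[ii]),
                 smoothed_height = s[apex],
                 left = rt[left], right = rt[right],
                 area = area, points = sum(y[ii] >= thr),
                 apex_index = apex, left_index = left, right_index = right),
            class = "chrom_peak")
}

#' Quantify one peptide form from MS1
#'
#' Sums the XICs of the first \code{n_isotopes} isotopologues, detects the
#' peak at the expected retention time, and integrates over shared
#' boundaries (so the area equals the sum of the per-isotopologue areas).
#'
#' @param run a \code{dia_run}.
#' @param form a \code{peptide_form}.
#' @param charge precursor charge.
#' @param expected_rt expected apex RT (minutes).
#' @param config quant configuration, see \code{.default_quant_config}.
#' @return one-row data.frame: rt_apex, height, left, right, area, points,
#'   detected.
#' @export
quantify_form <- function(run, form, charge, expected_rt,
                          config = list()) {
  cfg <- utils::modifyList(.default_quant_config(), config)
  env <- isotope_envelope(form, charge = charge, n_peaks = cfg$n_isotopes)
  rtr <- expected_rt + c(-1, 1) * (cfg$rt_tolerance_min + 1)
  traces <- extract_xic(run, env$mz, cfg$ppm_ms1, ms_level = 1L,
                        rt_range = rtr)
  summed <- traces[[1]]
  for (j in seq_along(traces)[-1])
    summed$intensity <- summed$intensity + traces[[j]]$intensity
  pk <- detect_peak(summed, expected_rt, cfg$rt_tolerance_min,
                    cfg$noise_floor)
  if (is.null(pk))
    return(data.frame(rt_apex = NA_real_, height = 0, left = NA_real_,
                      right = NA_real_, area = 0, points = 0L,
                      detected = FALSE))
  data.frame(rt_apex = pk$rt_apex, height = pk$height, left = pk$left,
             right = pk$right, area = pk$area, points = pk$points,
             detected = TRUE)
}

# ---- discriminating fragment ions -------------------------------------------

#' Fragment ions that distinguish the members of an isomer group
#'
#' Enumerates the b/y series of every member and reports each ion index
#' whose m/z differs between at least two members, with the member subset
#' sharing each m/z variant and the inter-site span the ion falls in
#' (cleavage position between consecutive candidate modification sites).
#'
#' @param group an \code{isomer_group}.
#' @param product_charge product ion charge.
#' @return data.frame: ion, index, label, span (0 = outside all spans),
#'   mz, members (comma-separated member indices sharing this variant).
#' @export
discriminating_ions <- function(group, product_charge = 1L) {
  members <- group$members
  if (length(members) < 2)
    return(data.frame(ion = character(0), index = integer(0),
                      label = character(0), span = integer(0),
                      mz = numeric(0), members = character(0)))
  frags <- lapply(members, fragment_mz_series,
                  product_charge = product_charge)
  n <- nchar(members[[1]]$sequence)
  sites <- group$sites
  out <- list()
  for (ion in c("b", "y")) {
    idxs <- sort(unique(frags[[1]]$index[frags[[1]]$ion == ion]))
    for (ix in idxs) {
      mzs <- vapply(frags, function(fr)
        fr$mz[fr$ion == ion & fr$index == ix], numeric(1))
      key <- round(mzs, 5)
      if (length(unique(key)) < 2) next
      cleave <- if (ion == "b") ix else n - ix # residues before the bond
      span <- if (length(sites) >= 2 && cleave >= sites[1] &&
                  cleave < sites[length(sites)])
        max(which(sites <= cleave)) else 0L
      for (v in unique(key)) {
        mem <- which(key == v)
        out[[length(out) + 1L]] <- data.frame(
          ion = ion, index = ix, label = paste0(ion, ix),
          span = span, mz = mzs[mem[1]],
          members = paste(mem, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(ion = character(0), index = integer(0),
                      label = character(0), span = integer(0),
                      mz = numeric(0), members = character(0)))
  do.call(rbind, out)
}

# smoothed MS2 XIC height at the MS1 apex RT for a set of ion m/z values
.ms2_heights_at <- function(run, mzs, window, apex_rt, ppm, rt_range) {
  traces <- extract_xic(run, mzs, ppm, ms_level = 2L, window = window,
                        rt_range = rt_range)
  if (length(mzs) == 1L) traces <- list(traces)
  vapply(traces, function(tr) {
    if (!nrow(tr)) return(0)
    s <- .smooth3(tr$intensity)
    s[which.min(abs(tr$rt - apex_rt))]
  }, numeric(1))
}

#' Split a co-eluting isobaric isomer group
#'
#' Positional isomers are identical at MS1; their proportions are
#' recovered from MS2 by linear equations on the peak heights of
#' discriminating fragment ions situated between consecutive modification
#' sites. For candidate sites s1 < ... < sk, each inter-site span j gives
#' an estimate of the cumulative fraction F_j (signal from members
#' modified at a site <= j): over the discriminating b ions of span j,
#' F_j = sum h(modified variant) / sum h(modified + unmodified variant),
#' with h the smoothed MS2 XIC height at the MS1 apex. y ions estimate
#' 1 - F_j analogously and the two are averaged. Member fractions are
#' first differences of F, clipped to >= 0 and renormalized.
#'
#' The \code{"nnls"} method instead solves the full ion-membership system
#' (per-ion normalized variant heights against member-indicator rows) by
#' nonnegative least squares; it handles groups whose members differ in
#' more than one placement.
#'
#' @param group an \code{isomer_group} (>= 2 members).
#' @param run a \code{dia_run}.
#' @param ms1_peak a \code{chrom_peak} (or one-row quantify_form output)
#'   locating the shared MS1 peak.
#' @param config quant configuration (\code{ppm_ms2},
#'   \code{split_method}).
#' @return an \code{isomer_split} list: fractions (named by member form
#'   id), cumulative, ions (heights used), low_confidence flag.
#' @export
split_isobaric <- function(group, run, ms1_peak, config = list()) {
  cfg <- utils::modifyList(.default_quant_config(), config)
  members <- group$members
  k <- length(members)
  stopifnot(k >= 2)
  ids <- vapply(members, form_id, "")
  apex <- if (!is.null(ms1_peak$rt_apex)) ms1_peak$rt_apex else ms1_peak$rt
  rtr <- c(ms1_peak$left, ms1_peak$right)
  if (anyNA(rtr)) rtr <- apex + c(-0.5, 0.5)
  wins <- attr(run, "windows")
  if (is.null(wins)) wins <- run_windows(run)
  wsel <- which(wins$low < group$mz & group$mz <= wins$high)
  if (!length(wsel)) stop("group precursor m/z outside all run windows")
  if (length(wsel) > 1)
    wsel <- wsel[which.min(abs((wins$low[wsel] + wins$high[wsel]) / 2 -
                                 group$mz))]
  window <- c(wins$low[wsel], wins$high[wsel])
  dions <- discriminating_ions(group)
  uniform <- stats::setNames(rep(1 / k, k), ids)

  # member -> distinctive variable site (spans method applies when every
  # member differs from the rest in exactly one placement position)
  var_site <- rep(NA_integer_, k)
  pl <- lapply(members, function(m) {
    p <- m$placements[m$placements != "prop"]
    stats::setNames(unname(p), .placement_positions(p))
  })
  common <- Reduce(intersect, lapply(pl, function(p)
    paste(names(p), p, sep = ":")))
  for (i in seq_len(k)) {
    own <- setdiff(paste(names(pl[[i]]), pl[[i]], sep = ":"), common)
    pos <- suppressWarnings(as.integer(sub(":.*", "", own)))
    if (length(pos) == 1L && !is.na(pos)) var_site[i] <- pos
  }
  use_spans <- cfg$split_method == "spans" && !anyNA(var_site) &&
    !anyDuplicated(var_site) && length(group$sites) == k &&
    all(sort(var_site) == group$sites)

  if (nrow(dions) == 0) {
    return(structure(list(fractions = uniform, cumulative = NULL,
                          ions = dions, low_confidence = TRUE,
                          method = "none"), class = "isomer_split"))
  }

  dions$height <- .ms2_heights_at(run, dions$mz, window, apex,
                                  cfg$ppm_ms2, rtr)

  if (use_spans) {
    ord <- order(var_site)
    sites <- sort(var_site)
    Fb <- Fy <- rep(NA_real_, k - 1)
    for (j in seq_len(k - 1)) {
      sp <- dions[dions$span == j, , drop = FALSE]
      if (!nrow(sp)) next
      # variant carried by members modified at a site <= j: for b ions the
      # prefix contains the modification; for y ions the suffix does not
      mem_le <- ord[seq_len(j)]
      has_le <- vapply(strsplit(sp$members, ","), function(m)
        all(as.integer(m) %in% mem_le), logical(1))
      for (ion in c("b", "y")) {
        sub <- sp[sp$ion == ion, , drop = FALSE]
        hle <- sub$height[has_le[sp$ion == ion]]
        hgt <- sub$height[!has_le[sp$ion == ion]]
        tot <- sum(hle) + sum(hgt)
        if (tot > 0) {
          if (ion == "b") Fb[j] <- sum(hle) / tot
          else Fy[j] <- sum(hle) / tot
        }
      }
    }
    Fj <- ifelse(is.na(Fb), Fy, ifelse(is.na(Fy), Fb, (Fb + Fy) / 2))
    low_conf <- all(is.na(Fj))
    if (low_conf) {
      frac <- uniform
    } else {
      # interpolate any unobserved span between known cumulative values
      Ffull <- c(0, Fj, 1)
      known <- which(!is.na(Ffull))
      Ffull <- stats::approx(known, Ffull[known], xout = seq_along(Ffull),
                             rule = 2)$y
      Ffull <- cummax(pmin(pmax(Ffull, 0), 1)) # monotone in [0, 1]
      x <- diff(Ffull)
      x <- pmax(x, 0)
      if (sum(x) == 0) x <- rep(1 / k, k)
      x <- x / sum(x)
      frac <- stats::setNames(numeric(k), ids)
      frac[ids[ord]] <- x
    }
    return(structure(list(fractions = frac,
                          cumulative = if (low_conf) NULL else Fj,
                          ions = dions, low_confidence = low_conf,
                          method = "spans"), class = "isomer_split"))
  }

  # nonnegative least squares over the full ion-membership matrix:
  # for each discriminating ion index, normalized variant heights estimate
  # the summed fractions of the members sharing that variant
  rows <- list(); rhs <- numeric(0)
  for (lab in unique(dions$label)) {
    sub <- dions[dions$label == lab, , drop = FALSE]
    tot <- sum(sub$height)
    if (tot <= 0) next
    for (r in seq_len(nrow(sub))) {
      ind <- numeric(k)
      ind[as.integer(strsplit(sub$members[r], ",")[[1]])] <- 1
      rows[[length(rows) + 1L]] <- ind
      rhs <- c(rhs, sub$height[r] / tot)
    }
  }
  if (!length(rows)) {
    return(structure(list(fractions = uniform, cumulative = NULL,
                          ions = dions, low_confidence = TRUE,
                          method = "nnls"), class = "isomer_split"))
  }
  A <- rbind(do.call(rbind, rows), rep(1, k))
  b <- c(rhs, 1)
  x <- if (requireNamespace("pracma", quietly = TRUE))
    pracma::lsqnonneg(A, b)$x
  else pmax(stats::coef(stats::lm.fit(A, b)), 0)
  if (sum(x) == 0) x <- rep(1 / k, k)
  x <- x / sum(x)
  structure(list(fractions = stats::setNames(x, ids), cumulative = NULL,
                 ions = dions, low_confidence = FALSE, method = "nnls"),
            class = "isomer_split")
}

#' @export
print.isomer_split <- function(x, ...) {
  cat("<isomer_split> (", x$method, ")\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

# ---- run-level orchestration -------------------------------------------------

#' Landmark retention-time calibration
#'
#' Locates each anchor form by its m/z-only maximal MS1 peak and fits a
#' linear map from library retention time to observed retention time.
#'
#' @param run a \code{dia_run}.
#' @param db a \code{target_db} with an \code{rt_lib} column.
#' @param n_anchors number of anchors (most intense located forms).
#' @param config quant configuration.
#' @return function mapping library RT to expected observed RT.
#' @export
calibrate_rt <- function(run, db, n_anchors = 12L, config = list()) {
  cfg <- utils::modifyList(.default_quant_config(), config)
  u <- db[!duplicated(round(db$mz, 4)), , drop = FALSE]
  traces <- extract_xic(run, u$mz, cfg$ppm_ms1, ms_level = 1L)
  if (nrow(u) == 1L) traces <- list(traces)
  obs <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (!nrow(tr) || all(tr$intensity <= 0)) return(NULL)
    j <- which.max(.smooth3(tr$intensity))
    data.frame(lib = u$rt_lib[i], obs = tr$rt[j], h = tr$intensity[j])
  }))
  if (is.null(obs) || nrow(obs) < 3) return(identity)
  obs <- obs[order(-obs$h), , drop = FALSE][seq_len(min(n_anchors,
                                                        nrow(obs))), ]
  fit <- stats::lm(obs ~ lib, data = obs)
  if (stats::coef(fit)[2] <= 0) return(identity) # degenerate anchor fit
  function(rt) unname(stats::predict(fit, data.frame(lib = rt)))
}

#' Quantify every target of a database in one DIA run
#'
#' For each (backbone, charge) the forms are grouped by precursor m/z;
#' each group is quantified once at MS1 (isomers share the precursor) at
#' its calibrated retention time, and groups with several members are
#' split by discriminating MS2 fragment ions. Areas of group members are
#' the group MS1 area times the isomer fraction.
#'
#' @param run a \code{dia_run}.
#' @param db a \code{target_db}; an \code{rt_lib} column drives RT
#'   assignment (required).
#' @param config quant configuration overrides (ppm_ms1 = 10,
#'   ppm_ms2 = 20, rt_tolerance_min = 0.5, n_isotopes = 3,
#'   split_method = "spans", min_points = 6, calibrate = TRUE).
#' @return data.frame (class \code{quant_table}): one row per form with
#'   rt_apex, area_group, fraction, area, points, detected,
#'   low_confidence, identified.
#' @export
quantify_run <- function(run, db, config = list()) {
  cfg <- utils::modifyList(.default_quant_config(), config)
  if (!nrow(db)) {
    warning("empty target database; nothing to quantify")
    return(structure(data.frame(), class = c("quant_table", "data.frame")))
  }
  if (!"rt_lib" %in% names(db))
    stop("target database needs an rt_lib column for RT assignment")
  run <- index_run(run)
  rt_map <- if (isTRUE(cfg$calibrate)) calibrate_rt(run, db, config = cfg)
            else identity
  out <- list()
  for (key in unique(paste(db$sequence, db$charge))) {
    sub <- db[paste(db$sequence, db$charge) == key, , drop = FALSE]
    forms <- lapply(seq_len(nrow(sub)), function(i) db_row_form(sub[i, ]))
    grps <- group_isobaric(forms, charge = sub$charge[1],
                           ppm_tol = cfg$ppm_ms1)
    for (g in grps) {
      ids <- vapply(g$members, form_id, "")
      rows <- sub[match(ids, sub$form_id), , drop = FALSE]
      exp_rt <- rt_map(mean(rows$rt_lib))
      q <- quantify_form(run, g$members[[1]], g$charge, exp_rt, cfg)
      if (length(g$members) > 1 && q$detected) {
        sp <- split_isobaric(g, run, as.list(q), cfg)
        frac <- sp$fractions[ids]
        lowc <- sp$low_confidence
      } else {
        frac <- rep(1 / length(ids), length(ids))
        lowc <- FALSE
      }
      res <- rows[, c("form_id", "protein", "start", "end", "sequence",
                      "placements", "charge", "mz")]
      res$rt_expected <- exp_rt
      res$rt_apex <- q$rt_apex
      res$left <- q$left; res$right <- q$right
      res$points <- q$points
      res$area_group <- q$area
      res$fraction <- as.numeric(frac)
      res$area <- q$area * as.numeric(frac)
      res$detected <- q$detected
      res$low_confidence <- lowc
      res$identified <- q$detected & q$points >= cfg$min_points & !lowc
      out[[length(out) + 1L]] <- res
    }
  }
  qt <- do.call(rbind, out)
  rownames(qt) <- NULL
  structure(qt, class = c("quant_table", "data.frame"))
}

#' Write a quantification table to CSV
#' @param qt a \code{quant_table}.
#' @param path CSV path.
#' @export
write_quant <- function(qt, path) {
  utils::write.csv(as.data.frame(qt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant
#' @export
read_quant <- function(path) {
  qt <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(placements = "character"))
  qt$placements[is.na(qt$placements)] <- ""
  structure(qt, class = c("quant_table", "data.frame"))
}
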