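# Synthetic DIA run generator with known ground truth. Emulates the
# acquisition model of a fast-gradient SWATH histone run (one MS1 scan
# followed by the scheme's MS2 windows per cycle) so that every pipeline
# stage can be exercised and scored against injected parameters.

#' Construct a synthetic-truth specification
#'
#' @param forms data.frame with one row per peptide form: form_id, protein,
#'   start, end, sequence, placements (serialized), charge, rt_min (apex
#'   retention time, minutes), sigma_s (Gaussian peak sigma, seconds), area
#'   (total MS1 area, intensity x minutes), group (isomer-group id; members
#'   of one group co-elute and share precursor m/z), fraction (isomer
#'   fraction within the group, summing to 1 per group).
#' @param scheme a \code{window_scheme} (defines windows and cycle time).
#' @param gradient_min gradient length in minutes.
#' @param noise_mult_sigma sigma of per-peak multiplicative log-normal
#'   noise (0 = noiseless).
#' @param noise_floor upper bound of per-peak additive uniform noise.
#' @param rt_jitter_rel between-replicate retention-time jitter as a
#'   fraction of each apex RT (sigma of the relative shift), applied per
#'   isomer group; 0.01 emulates 1 percent run-to-run RT variation.
#' @param frag_yield fragment-to-precursor intensity scale.
#' @param min_peak_intensity peaks below this intensity are not written.
#' @param seed base random seed; replicate r uses seed + r internally.
#' @return object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(forms, scheme, gradient_min = 10,
                            noise_mult_sigma = 0, noise_floor = 0,
                            rt_jitter_rel = 0, frag_yield = 0.5,
                            min_peak_intensity = 1e-2, seed = 1L) {
  stopifnot(is.data.frame(forms),
            all(c("form_id", "sequence", "placements", "charge", "rt_min",
                  "sigma_s", "area", "group", "fraction") %in% names(forms)))
  fr <- tapply(forms$fraction, forms$group, sum)
  if (any(abs(fr - 1) > 1e-9))
    stop("isomer fractions must sum to 1 within each group")
  if (any(forms$rt_min < 0 | forms$rt_min > gradient_min))
    stop("apex retention times must lie within the gradient")
  if (any(forms$sigma_s <= 0)) stop("peak sigma must be positive")
  structure(list(forms = forms, scheme = scheme,
                 gradient_min = gradient_min,
                 noise_mult_sigma = noise_mult_sigma,
                 noise_floor = noise_floor,
                 rt_jitter_rel = rt_jitter_rel,
                 frag_yield = frag_yield,
                 min_peak_intensity = min_peak_intensity,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$forms), " forms in ",
      length(unique(x$forms$group)), " groups, ", x$gradient_min,
      "-min gradient, ", nrow(x$scheme), " windows, cycle ",
      sprintf("%.3f", cycle_time(x$scheme)), " s\n", sep = "")
  invisible(x)
}

#' Target database corresponding to a truth specification
#'
#' The searchable side of the ground truth: same forms, with neutral mass,
#' precursor m/z and a library retention time column (\code{rt_lib}) for
#' RT-driven peak assignment.
#'
#' @param truth a \code{synthetic_truth}.
#' @return a \code{target_db} data.frame.
#' @export
truth_target_db <- function(truth) {
  f <- truth$forms
  mass <- vapply(seq_len(nrow(f)), function(i)
    monoisotopic_mass(db_row_form(f[i, ])), numeric(1))
  db <- data.frame(form_id = f$form_id, protein = f$protein,
                   start = f$start, end = f$end, sequence = f$sequence,
                   placements = f$placements, neutral_mass = mass,
                   charge = f$charge, mz = precursor_mz(mass, f$charge),
                   rt_lib = f$rt_min, stringsAsFactors = FALSE)
  class(db) <- c("target_db", "data.frame")
  db
}

# fragment base intensities for one backbone: uniform(0.2, 1) per ion
# label, drawn from a backbone-specific stream so they are identical for
# every member of an isomer group and across replicates
.frag_base <- function(sequence, labels, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  h <- sum(utf8ToInt(sequence) * seq_len(nchar(sequence)))
  set.seed((seed + h) %% 2147483647L)
  stats::setNames(stats::runif(length(labels), 0.2, 1), labels)
}

#' Simulate a DIA run from a truth specification
#'
#' Cycles at fixed cadence across the gradient: each MS1 spectrum carries
#' every form's first-3-isotope envelope scaled by a Gaussian elution
#' profile; each MS2 window spectrum carries the b/y fragments of forms
#' whose precursor falls in that window, with isomer-group fragment
#' intensities mixed according to the truth fractions. Per-peak
#' multiplicative log-normal noise and an additive floor are applied.
#' Fully reproducible from (seed, replicate).
#'
#' @param truth a \code{synthetic_truth}.
#' @param replicate replicate index; changes the noise and RT-jitter draw
#'   but not the underlying truth.
#' @return a \code{dia_run}.
#' @export
simulate_run <- function(truth, replicate = 1L) {
  scheme <- truth$scheme
  ct_s <- cycle_time(scheme)
  ct_min <- ct_s / 60
  n_cyc <- max(1L, floor(truth$gradient_min / ct_min))
  nw <- nrow(scheme)
  forms <- truth$forms
  set.seed((truth$seed * 1009L + as.integer(replicate)) %% 2147483647L)

  # per-group RT jitter for this replicate
  groups <- unique(forms$group)
  jit <- stats::setNames(stats::rnorm(length(groups), 0,
                                      truth$rt_jitter_rel), groups)
  rt_obs <- forms$rt_min * (1 + jit[forms$group])

  # precompute per form: envelope, fragments, window, active cycles
  cyc_rt <- (seq_len(n_cyc) - 1) * ct_min # cycle-start RT (MS1 scan time)
  ms1_acc <- vector("list", n_cyc)
  ms2_acc <- replicate(n_cyc, vector("list", nw), simplify = FALSE)
  centers <- (scheme$low + scheme$high) / 2
  for (i in seq_len(nrow(forms))) {
    f <- db_row_form(forms[i, ])
    mass <- monoisotopic_mass(f)
    z <- forms$charge[i]
    env <- isotope_envelope(f, charge = z, n_peaks = 3)
    w_iso <- env$intensity / sum(env$intensity)
    pmz <- precursor_mz(mass, z)
    win <- which(scheme$low < pmz & pmz <= scheme$high)
    if (length(win) > 1) win <- win[which.min(abs(centers[win] - pmz))]
    if (!length(win))
      warning("precursor m/z ", round(pmz, 3), " of ", forms$form_id[i],
              " outside all windows; skipped in MS2")
    frag <- fragment_mz_series(f, product_charge = 1L)
    base <- .frag_base(forms$sequence[i], frag$label, truth$seed)
    sig_min <- forms$sigma_s[i] / 60
    # cycles where the Gaussian is above the write threshold
    g_cyc <- stats::dnorm(cyc_rt, rt_obs[i], sig_min)
    hmax <- forms$area[i] * max(w_iso)
    active <- which(g_cyc * hmax > truth$min_peak_intensity / 10)
    for (cix in active) {
      g1 <- stats::dnorm(cyc_rt[cix], rt_obs[i], sig_min)
      ms1_acc[[cix]][[length(ms1_acc[[cix]]) + 1L]] <-
        cbind(env$mz, forms$area[i] * w_iso * g1)
      if (length(win)) {
        t2 <- cyc_rt[cix] + win * ct_min / (nw + 1)
        g2 <- stats::dnorm(t2, rt_obs[i], sig_min)
        acc <- ms2_acc[[cix]][[win]]
        ms2_acc[[cix]][[win]] <-
          c(acc, list(cbind(frag$mz,
                            truth$frag_yield * forms$area[i] *
                              unname(base[frag$label]) * g2)))
      }
    }
  }

  finalize <- function(pieces) {
    if (!length(pieces))
      return(cbind(numeric(0), numeric(0)))
    m <- do.call(rbind, pieces)
    key <- round(m[, 1], 6)
    inten <- tapply(m[, 2], key, sum)
    mz <- as.numeric(names(inten))
    inten <- as.numeric(inten)
    if (truth$noise_mult_sigma > 0)
      inten <- inten * exp(stats::rnorm(length(inten), 0,
                                        truth$noise_mult_sigma))
    if (truth$noise_floor > 0)
      inten <- inten + stats::runif(length(inten), 0, truth$noise_floor)
    keep <- inten >= truth$min_peak_intensity
    ord <- order(mz[keep])
    cbind(mz[keep][ord], inten[keep][ord])
  }

  spectra <- vector("list", n_cyc * (nw + 1L))
  scan <- 0L
  for (cix in seq_len(n_cyc)) {
    scan <- scan + 1L
    m <- finalize(ms1_acc[[cix]])
    spectra[[scan]] <- list(scan = scan, ms_level = 1L, rt = cyc_rt[cix],
                            mz = m[, 1], intensity = m[, 2])
    for (w in seq_len(nw)) {
      scan <- scan + 1L
      m <- finalize(ms2_acc[[cix]][[w]])
      spectra[[scan]] <- list(scan = scan, ms_level = 2L,
                              rt = cyc_rt[cix] + w * ct_min / (nw + 1),
                              mz = m[, 1], intensity = m[, 2],
                              window_low = scheme$low[w],
                              window_high = scheme$high[w],
                              precursor_mz = centers[w])
    }
  }
  dia_run(spectra, cycle_time_s = ct_s)
}

# Bundled mature histone sequences (initiator Met removed; community
# numbering). H3.1 = P68431, H4 = P62805.
.HISTONE_SEQS <- c(
  H3 = paste0("ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQ",
              "KSTELLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLC",
              "AIHAKRVTIMPKDIQLARRIRGERA"),
  H4 = paste0("SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETR",
              "GVLKVFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG")
)

#' Default histone ground truth
#'
#' A bundled truth built from the mature human H3.1 and H4 sequences:
#' derivatized tryptic peptides carrying mono-acetyl and mono-methyl-state
#' lysine forms, precursors restricted to m/z 300-900, a 10-min gradient,
#' and a 42-variable-window scheme with a 0.761-s cycle. It includes the
#' H4 4-17 mono-acetyl positional-isomer quartet at fractions
#' (0.4, 0.3, 0.2, 0.1) for K5/K8/K12/K16 and trimethyl/acetyl
#' pseudo-isobaric pairs on the same peptides.
#'
#' @param seed random seed controlling abundances, retention times and all
#'   simulation noise.
#' @param gradient_min gradient length (minutes).
#' @param noise_mult_sigma,noise_floor,rt_jitter_rel noise model
#'   passed to [synthetic_truth()]; defaults give 1\% multiplicative
#'   peak noise and 1\% between-replicate RT jitter.
#' @param n_windows number of variable windows.
#' @return a \code{synthetic_truth}.
#' @export
default_histone_truth <- function(seed = 1L, gradient_min = 10,
                                  noise_mult_sigma = 0.01,
                                  noise_floor = 0,
                                  rt_jitter_rel = 0.01,
                                  n_windows = 42L) {
  db <- build_target_db(.HISTONE_SEQS,
                        allowed_mods = list(K = c("ac", "me1", "me2", "me3")),
                        max_mods = 1L, charges = 2:4,
                        mz_range = c(300, 900), min_length = 4L)
  # one charge state per form: the lowest charge landing in range
  db <- db[order(db$form_id, db$charge), ]
  db <- db[!duplicated(db$form_id), ]
  # group positional isomers per (sequence, placSet composition): reuse the
  # grouping operation per backbone/charge
  forms_all <- list()
  set.seed(seed)
  for (key in unique(paste(db$sequence, db$charge))) {
    sub <- db[paste(db$sequence, db$charge) == key, , drop = FALSE]
    forms <- lapply(seq_len(nrow(sub)), function(i) db_row_form(sub[i, ]))
    grps <- group_isobaric(forms, charge = sub$charge[1], ppm_tol = 10)
    for (g in grps) {
      ids <- vapply(g$members, form_id, "")
      rows <- sub[match(ids, sub$form_id), , drop = FALSE]
      k <- nrow(rows)
      if (identical(sort(ids),
                    sort(c("H4_4-17_K5ac", "H4_4-17_K8ac",
                           "H4_4-17_K12ac", "H4_4-17_K16ac")))) {
        frac <- c(0.4, 0.3, 0.2, 0.1)[match(rows$form_id,
                                            c("H4_4-17_K5ac", "H4_4-17_K8ac",
                                              "H4_4-17_K12ac",
                                              "H4_4-17_K16ac"))]
      } else if (k > 1) {
        w <- stats::runif(k, 0.5, 1.5)
        frac <- round(w / sum(w), 4)
        frac[k] <- 1 - sum(frac[-k])
      } else frac <- 1
      rows$group <- paste0(rows$sequence[1], "/z", rows$charge[1], "/",
                           sprintf("%.3f", g$mz))
      rows$fraction <- frac
      forms_all[[length(forms_all) + 1L]] <- rows
    }
  }
  f <- do.call(rbind, forms_all)
  groups <- unique(f$group)
  # spread group apexes evenly over the usable gradient, interleaving
  # backbones: modification families of one backbone share fragment m/z
  # (their unmodified-variant ions are identical), so they are kept far
  # apart in retention time to avoid cross-contamination of the splits
  backbone <- sub("/z.*", "", groups)
  rank_in_bb <- stats::ave(seq_along(groups), backbone, FUN = seq_along)
  slots <- seq(0.08, 0.92, length.out = length(groups)) * gradient_min
  rt_by_group <- stats::setNames(numeric(length(groups)),
                                 groups[order(rank_in_bb, backbone)])
  rt_by_group[] <- slots
  f$rt_min <- as.numeric(rt_by_group[f$group])
  garea <- stats::setNames(10^stats::runif(length(groups), 4.5, 6.5), groups)
  f$area <- garea[f$group] * f$fraction
  f$sigma_s <- 2.5
  scheme <- variable_scheme(f$mz, n_windows = n_windows, min_width = 5,
                            overlap = 1, range = c(295, 905),
                            ms1_ms = 100, ms2_ms = 10, overhead_ms = 5.6)
  synthetic_truth(f[, c("form_id", "protein", "start", "end", "sequence",
                        "placements", "charge", "rt_min", "sigma_s", "area",
                        "group", "fraction")],
                  scheme, gradient_min = gradient_min,
                  noise_mult_sigma = noise_mult_sigma,
                  noise_floor = noise_floor,
                  rt_jitter_rel = rt_jitter_rel,
                  seed = seed)
}

#' Write the truth table to CSV
#' @param truth a \code{synthetic_truth}.
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth$forms, path, row.names = FALSE)
  invisible(path)
}
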