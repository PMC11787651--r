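# Independent oracles and fixture builders used across the suite.

# Brute-force isotope distribution: enumerate heavy-isotope counts per
# element with exact multinomial probabilities and aggregate by total
# extra-neutron count. Deliberately a different route from the package's
# truncated-convolution implementation.
oracle_isotope_dist <- function(comp, n_peaks = 3) {
  iso_tab <- list(
    C = list(extra = c(0, 1), ab = c(0.9893, 0.0107)),
    H = list(extra = c(0, 1), ab = c(0.999885, 0.000115)),
    N = list(extra = c(0, 1), ab = c(0.99636, 0.00364)),
    O = list(extra = c(0, 1, 2), ab = c(0.99757, 0.00038, 0.00205)),
    S = list(extra = c(0, 1, 2, 4), ab = c(0.9499, 0.0075, 0.0425, 1e-04)),
    P = list(extra = 0, ab = 1)
  )
  # per-element distribution over extra neutrons by explicit enumeration
  elem_dist <- function(el, n_atoms) {
    tab <- iso_tab[[el]]
    k <- length(tab$ab)
    out <- numeric(n_peaks)
    # enumerate counts of each heavy isotope up to n_peaks - 1 atoms each
    grid <- expand.grid(rep(list(0:(n_peaks - 1)), k - 1))
    if (k == 1) return(c(1, numeric(n_peaks - 1)))
    for (r in seq_len(nrow(grid))) {
      heavy <- as.integer(grid[r, ])
      if (sum(heavy) > n_atoms) next
      extra <- sum(heavy * tab$extra[-1])
      if (extra >= n_peaks) next
      counts <- c(n_atoms - sum(heavy), heavy)
      out[extra + 1] <- out[extra + 1] +
        stats::dmultinom(counts, prob = tab$ab)
    }
    out
  }
  dists <- lapply(names(comp), function(el) elem_dist(el, comp[[el]]))
  # combine by enumerating extra-neutron allocations across elements
  total <- c(1, numeric(n_peaks - 1))
  for (d in dists) {
    new <- numeric(n_peaks)
    for (a in seq_len(n_peaks)) for (b in seq_len(n_peaks - a + 1))
      new[a + b - 1] <- new[a + b - 1] + total[a] * d[b]
    total <- new
  }
  total / max(total)
}

# Compact ground truth: the H4 4-17 mono-acetyl quartet plus two
# well-separated singleton peptides, short gradient, few windows.
small_truth <- function(fractions = c(0.4, 0.3, 0.2, 0.1),
                        gradient_min = 3, n_windows = 8,
                        noise_mult_sigma = 0, rt_jitter_rel = 0,
                        seed = 1L, quartet_rt = 0.5 * gradient_min,
                        sigma_s = 2.5, group_area = 1e6) {
  quartet <- enumerate_forms("GKGGKGLGKGGAKR", list(K = "ac"), 1,
                             protein = "H4", start = 4)
  quartet <- quartet[vapply(quartet, function(f)
    any(f$placements == "ac"), logical(1))]
  ids <- vapply(quartet, form_id, "")
  ser <- vapply(quartet, function(x)
    histoneDIA:::.serialize_placements(x$placements), "")
  f <- data.frame(form_id = ids, protein = "H4", start = 4L, end = 17L,
                  sequence = "GKGGKGLGKGGAKR", placements = ser,
                  charge = 2L, rt_min = quartet_rt, sigma_s = sigma_s,
                  area = group_area * fractions, group = "H4_4-17_ac1",
                  fraction = fractions, stringsAsFactors = FALSE)
  singles <- list(
    apply_propionylation(peptide_form("KSTGGKAPR", protein = "H3",
                                      start = 9)),
    apply_propionylation(peptide_form("KVLR", protein = "H4", start = 20)))
  for (i in seq_along(singles)) {
    s <- singles[[i]]
    f <- rbind(f, data.frame(
      form_id = form_id(s), protein = s$protein, start = s$start,
      end = s$end, sequence = s$sequence,
      placements = histoneDIA:::.serialize_placements(s$placements),
      charge = 2L, rt_min = gradient_min * (0.55 + 0.15 * i),
      sigma_s = sigma_s,
      area = group_area / (2 * i), group = paste0("single", i),
      fraction = 1, stringsAsFactors = FALSE))
  }
  mzs <- precursor_mz(vapply(seq_len(nrow(f)), function(i)
    monoisotopic_mass(db_row_form(f[i, ])), numeric(1)), f$charge)
  scheme <- variable_scheme(mzs, n_windows = n_windows, min_width = 5,
                            overlap = 1, range = c(295, 905))
  synthetic_truth(f, scheme, gradient_min = gradient_min,
                  noise_mult_sigma = noise_mult_sigma,
                  rt_jitter_rel = rt_jitter_rel, seed = seed)
}

# analytic Gaussian XIC trace sampled at a fixed cycle time
gaussian_trace <- function(area = 1e5, rt_apex = 2, sigma_s = 2.5,
                           cycle_s = 0.761, t_max = 4) {
  rt <- seq(0, t_max, by = cycle_s / 60)
  structure(data.frame(rt = rt,
                       intensity = area * dnorm(rt, rt_apex, sigma_s / 60)),
            class = c("xic_trace", "data.frame"), mz = NA, ppm = NA)
}
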