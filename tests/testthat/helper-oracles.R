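# Exhaustive grid-search oracle for the pigment peak: scores every
# candidate on a fine grid with the closed-form amplitude. Independent of
# the package's nested grid + local-refinement optimizer.
grid_search_lmax <- function(spectrum, step = 0.01, bounds = c(300, 700),
                             window = c(300, 700), include_beta = TRUE) {
  keep <- spectrum$wavelength_nm >= window[1] & spectrum$wavelength_nm <= window[2]
  wl <- spectrum$wavelength_nm[keep]
  y <- spectrum$absorbance[keep] / max(spectrum$absorbance[keep])
  cands <- seq(bounds[1], bounds[2], by = step)
  best <- NA_real_
  best_rss <- Inf
  # chunked to keep the candidate-template matrix small
  for (chunk in split(cands, ceiling(seq_along(cands) / 2000))) {
    tm <- vapply(chunk, function(l) govardovskii_a1(wl, l, include_beta),
                 numeric(length(wl)))
    cty <- as.numeric(crossprod(tm, y))
    ctt <- colSums(tm^2)
    rss <- sum(y^2) - cty^2 / ctt
    rss[cty <= 0] <- Inf
    j <- which.min(rss)
    if (rss[j] < best_rss) {
      best_rss <- rss[j]
      best <- chunk[j]
    }
  }
  best
}
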