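# Independent brute-force oracles used to cross-check the package's
# implementations, deliberately written as literal definitions.

# pairwise Mann-Whitney AUC: mean over all (pos, neg) pairs of
# [s_pos > s_neg] + 0.5 [s_pos == s_neg]
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# literal index-scan peak detector: check the step definition at every
# index, then extend the monotone flanks outward for the width
oracle_peaks <- function(x, min_steps, step_s = 30) {
  n <- length(x)
  rows <- list()
  for (i in seq_len(n)) {
    if (i - min_steps < 1L || i + min_steps > n) next
    ok_up <- all(vapply(seq_len(min_steps),
                        function(j) x[i - j + 1L] > x[i - j], logical(1)))
    ok_dn <- all(vapply(seq_len(min_steps),
                        function(j) x[i + j - 1L] > x[i + j], logical(1)))
    if (!(ok_up && ok_dn)) next
    s <- i; while (s - 1L >= 1L && x[s - 1L] < x[s]) s <- s - 1L
    e <- i; while (e + 1L <= n && x[e + 1L] < x[e]) e <- e + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      apex_index = i, height = x[i],
      width = (e - s) * step_s / 60,
      rise_steps = i - s, fall_steps = e - i)
  }
  if (!length(rows))
    return(data.frame(apex_index = integer(), height = numeric(),
                      width = numeric(), rise_steps = integer(),
                      fall_steps = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small uniform grid in seconds
grid_s <- function(minutes, step_s = 30)
  seq(0, minutes * 60, by = step_s)

# a compact film summary with configurable per-class film counts and
# uniform screening counts, for split-enumeration properties
toy_film_summary <- function(films_per_class = c(2L, 3L, 2L, 2L),
                             n_screenings = 10L) {
  cls <- rep(c("0", "6", "12", "16"), times = films_per_class)
  data.frame(
    film_title = sprintf("film %s-%d", cls,
                         unlist(lapply(films_per_class, seq_len))),
    age_class = factor(cls, levels = c("0", "6", "12", "16")),
    n_screenings = n_screenings,
    stringsAsFactors = FALSE)
}

# a small, quick synthetic study (short films, few screenings)
quick_study <- function(seed = 1, separation = 5, n_films = c(2L, 2L, 2L, 2L),
                        screenings_per_film = 4L, noise_sd = 0.02,
                        n_compounds = 1L) {
  comps <- lapply(seq_len(n_compounds), function(i)
    list(id = sprintf("m%02d", i), name = NULL, scale = 1 / i,
         noise_sd = noise_sd))
  spec <- study_spec(
    profiles = default_profiles(separation = separation,
                                base_amplitude = 600,
                                n_films = n_films,
                                screenings_per_film = screenings_per_film,
                                film_length_min = c(40, 50)),
    compounds = comps, seed = seed)
  generate_study(spec)
}
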