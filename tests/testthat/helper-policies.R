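# shorthand constructors used across the suite

policy_at <- function(domain, z = 0, ...) {
  overrides <- list(...)
  d <- responder_defaults()
  for (nm in names(overrides)) d[[domain]][[nm]] <- overrides[[nm]]
  make_responder(z = z, domain = domain, defaults = d)
}

training_policies <- function(z = 0) {
  doms <- c("response_inhibition", "interference_control", "verbal_wm",
            "visuospatial_wm", "switching", "matching")
  stats::setNames(lapply(doms, function(d) make_responder(z = z, domain = d)),
                  doms)
}

# hand-built flanker log with fixed cell means, for scoring identities
ant_log_from_means <- function(means, n_per_cell = 4) {
  cells <- expand.grid(cue = c("none", "centre", "double", "spatial"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$cue[i], cells$congruency[i], sep = ".")
    data.frame(task = "ant", phase = "experimental", block = 1L,
               index = NA_integer_, cue = cells$cue[i],
               congruency = cells$congruency[i],
               rt = rep(means[[key]], n_per_cell),
               responded = TRUE, correct = TRUE, stringsAsFactors = FALSE)
  }))
  rows$index <- seq_len(nrow(rows))
  class(rows) <- c("trial_log", class(rows))
  rows
}
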