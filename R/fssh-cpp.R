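# R-side wrapper of the compiled propagator; packs the model term table
# and rebuilds the same `sh_trajectory` structure the reference engine
# returns.

.TERM_CODES <- c(harm = 1L, morse = 2L, rep = 3L, dwell = 4L,
                 quart = 5L, lin = 6L)

.model_data_cpp <- function(model) {
  tt <- model$terms
  list(
    term_state = as.integer(tt$state - 1L),
    term_coord = as.integer(tt$coord - 1L),
    term_type = unname(.TERM_CODES[tt$type]),
    term_p1 = as.numeric(tt$p1),
    term_p2 = as.numeric(tt$p2),
    term_p3 = as.numeric(tt$p3),
    origins = as.numeric(model$origins),
    Vconst = model$coupling + model$soc,
    is_triplet = as.integer(model$states$multiplicity == "triplet"),
    masses = as.numeric(model$masses))
}

.run_trajectory_cpp <- function(model, q, p, state, config, seed) {
  set.seed(seed)
  out <- .fssh_run_cpp(.model_data_cpp(model), q, p, as.integer(state),
                       config)
  reasons <- c("internal_conversion", "triplet_trapped", "timeout", "failed")
  reason <- reasons[out$reason]
  failed <- reason == "failed"
  man_final <- ifelse(out$final_manifold == 1, "triplet", "singlet")
  termination <- list(
    reason = reason,
    manifold = if (failed) NA_character_
               else if (reason == "internal_conversion") "singlet"
               else if (reason == "triplet_trapped") "triplet"
               else man_final[out$final_state],
    final_state = out$final_state,
    time = out$time,
    final_label = if (failed) NA_character_
                  else .state_labels(man_final)[out$final_state])
  pos <- out$positions
  colnames(pos) <- model$coords
  hops <- data.frame(time = as.numeric(out$hop_time),
                     from = as.integer(out$hop_from),
                     to = as.integer(out$hop_to),
                     accepted = as.integer(out$hop_accepted) == 1L)
  man <- ifelse(as.integer(out$manifold) == 1, "triplet", "singlet")
  rank <- as.integer(out$rank)
  structure(list(
    times = as.numeric(out$times), positions = pos,
    momenta = out$momenta, active = as.integer(out$active),
    energies = out$energies, populations = out$populations,
    manifold = man,
    label = ifelse(man == "triplet", paste0("T", rank),
                   paste0("S", rank - 1L)),
    total_energy = as.numeric(out$total_energy),
    hops = hops, termination = termination, seed = seed, config = config,
    failed = failed
  ), class = "sh_trajectory")
}
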