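#' Define a communicating agent
#'
#' An agent owns an estimator bank and a loop configuration. Dialogue acts
#' on one designated component (`component` index, default the first):
#' the sender runs its two-stage loop to turn its internal estimate into a
#' signal in sensorimotor space, and the receiver applies its own (similar
#' but not identical) component to reconstruct the sender's estimate.
#'
#' @param bank An [estimator_bank()] or a single [make_component()].
#' @param loop A [loop_config()].
#' @param role `"sender"` or `"receiver"` (informational).
#' @param component Index of the component used for dialogue.
#' @return An `agent`.
#' @export
agent <- function(bank, loop = loop_config(), role = c("sender", "receiver"),
                  component = 1L) {
  role <- match.arg(role)
  if (inherits(bank, "estimator_component")) bank <- estimator_bank(list(bank))
  stopifnot(inherits(bank, "estimator_bank"), inherits(loop, "loop_config"),
            component >= 1, component <= length(bank$components))
  structure(list(bank = bank, loop = loop, role = role,
                 component = as.integer(component)),
            class = "agent")
}

agent_component <- function(ag) ag$bank$components[[ag$component]]

set_agent_component <- function(ag, comp) {
  ag$bank$components[[ag$component]] <- comp
  ag
}

#' Perturb an agent's operator parameters
#'
#' Models the receiver having a similar-but-not-identical version of the
#' sender's estimator: every component's `A` and `b` get zero-mean
#' Gaussian noise whose sd is `delta` times the root-mean-square of that
#' parameter block's entries, so the relative parameter RMS difference is
#' about `delta`. Condition caps are re-enforced afterwards; the drift
#' anchors move with the perturbation (the copy is a distinct individual).
#' `delta = 0` returns an exact copy. Consumes the current RNG state.
#'
#' @param ag An [agent()].
#' @param delta Non-negative relative perturbation size.
#' @return The perturbed `agent`.
#' @export
perturb_agent <- function(ag, delta) {
  stopifnot(inherits(ag, "agent"), delta >= 0)
  if (delta == 0) return(ag)
  ag$bank$components <- lapply(ag$bank$components, function(comp) {
    rms_A <- sqrt(mean(comp$A^2))
    comp$A <- comp$A + matrix(stats::rnorm(length(comp$A), sd = delta * rms_A),
                              nrow(comp$A), ncol(comp$A))
    rms_b <- sqrt(mean(comp$b^2))
    if (rms_b > 0) comp$b <- comp$b + stats::rnorm(length(comp$b), sd = delta * rms_b)
    if (comp$n == comp$m && kappa(comp$A, exact = TRUE) > comp$cond_cap) {
      comp$A <- clip_condition(comp$A, comp$cond_cap)
    }
    comp$A0 <- comp$A
    comp$b0 <- comp$b
    comp
  })
  ag
}

#' Describe the communication channel
#'
#' @param noise_sd Non-negative sd of additive channel noise.
#' @param gain_loss Multiplicative attenuation in (0, 1].
#' @return A `channel_config`.
#' @export
channel_config <- function(noise_sd = 0, gain_loss = 1) {
  stopifnot(noise_sd >= 0, gain_loss > 0, gain_loss <= 1)
  structure(list(noise_sd = noise_sd, gain_loss = gain_loss),
            class = "channel_config")
}

#' Transmit a signal through the channel
#'
#' `u' = gain_loss * u_hat + noise`; exact when the channel is noiseless
#' with unit gain. Consumes the current RNG state when noisy.
#'
#' @param u_hat Signal vector to transmit.
#' @param channel A [channel_config()].
#' @return The received vector `u'`.
#' @export
transmit <- function(u_hat, channel = channel_config()) {
  stopifnot(inherits(channel, "channel_config"))
  u <- channel$gain_loss * u_hat
  if (channel$noise_sd > 0) u <- u + stats::rnorm(length(u), sd = channel$noise_sd)
  u
}

#' Reconstruct the sender's estimate from a received signal
#'
#' Stage-1 (forward) use only: the receiver applies its own component to
#' the received signal, yielding `x' = X'(u')`, its reconstruction of the
#' sender's internal estimate.
#'
#' @param ag The receiving [agent()].
#' @param u_prime Received signal vector.
#' @return The reconstruction `x'`.
#' @export
receive <- function(ag, u_prime) {
  stopifnot(inherits(ag, "agent"))
  apply_component(agent_component(ag), u_prime)
}

#' Run an alternating dialogue between two agents
#'
#' Each turn, the current speaker runs one two-stage cycle on its pending
#' input (the sender starts from `u_init`; afterwards each agent's pending
#' input is the signal it last received), transmits the inverted signal
#' through the channel, and the listener reconstructs the speaker's
#' estimate with its own component. Both agents' components drift between
#' turns at their own timescales. A diverged inversion flags the turn and
#' the dialogue continues with held buffers.
#'
#' @param sender,receiver [agent()]s with dimension-compatible components.
#' @param channel A [channel_config()].
#' @param n_turns Number of turns (>= 1).
#' @param u_init Initial stage-1 input for the sender.
#' @return A `dialogue_trace` tibble, one row per turn: `turn`, `speaker`
#'   (`"sender"`/`"receiver"`), the transmitted `u_hat`, received
#'   `u_prime`, the speaker's buffered estimate `x`, the listener's
#'   reconstruction `x_prime`, and
#'   `reconstruction_error = ||x' - x|| / ||x||`.
#' @export
run_dialogue <- function(sender, receiver, channel = channel_config(),
                         n_turns, u_init) {
  stopifnot(inherits(sender, "agent"), inherits(receiver, "agent"), n_turns >= 1)
  agents <- list(sender = sender, receiver = receiver)
  buffers <- list(
    sender = loop_buffers(agent_component(sender)$m, agent_component(sender)$n),
    receiver = loop_buffers(agent_component(receiver)$m, agent_component(receiver)$n)
  )
  pending <- list(sender = u_init, receiver = NULL)
  rows <- vector("list", n_turns)
  for (turn in seq_len(n_turns)) {
    who <- if (turn %% 2 == 1) "sender" else "receiver"
    other <- setdiff(c("sender", "receiver"), who)
    sp <- agents[[who]]
    comp <- agent_component(sp)
    u_in <- pending[[who]]
    if (is.null(u_in)) stop("no pending input for ", who, call. = FALSE)
    buf <- run_stage1(comp, u_in, buffers[[who]], time = turn)
    st2 <- run_stage2(comp, buf, sp$loop$inversion, time = turn)
    buffers[[who]] <- st2$buffers
    u_hat <- st2$buffers$u_buf
    u_prime <- transmit(u_hat, channel)
    x_sp <- st2$buffers$x_buf
    x_prime <- receive(agents[[other]], u_prime)
    pending[[other]] <- u_prime
    recon_err <- sqrt(sum((x_prime - x_sp)^2)) /
      max(sqrt(sum(x_sp^2)), .Machine$double.eps)
    rows[[turn]] <- tibble::tibble(
      turn = turn, speaker = who,
      u_hat = list(u_hat), u_prime = list(u_prime),
      x = list(x_sp), x_prime = list(x_prime),
      reconstruction_error = recon_err,
      converged = st2$result$converged, diverged = st2$result$diverged
    )
    # both individuals keep changing slowly between turns
    agents <- lapply(agents, function(ag) {
      cm <- agent_component(ag)
      if (cm$drift_sd > 0) ag <- set_agent_component(ag, drift_parameters(cm, ag$loop$cycle_period))
      ag
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dialogue_trace", class(out))
  out
}
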