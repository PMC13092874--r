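#' Cognitive parameters of the RLWM agent
#'
#' The agent combines an incremental reinforcement-learning (RL) module with a
#' capacity-limited, decaying working-memory (WM) module. Both update expected
#' reward by the delta rule; the WM learning rate is fixed at 1 (one-shot
#' updating). Negative prediction errors are down-weighted by `bias` in both
#' modules (`bias = 1` means total neglect of negative feedback). WM values
#' decay toward their initial value `1/3` at rate `phi` every trial. The two
#' modules' softmax policies are mixed with weight
#' `W_WM = rho * min(1, capacity / set_size)`.
#'
#' @param alpha_rl RL learning rate, in (0,1).
#' @param bias Negative-feedback neglect, in (0,1).
#' @param phi WM decay rate, in (0,1).
#' @param rho Propensity to rely on WM, in (0,1).
#' @param capacity WM capacity C, in (2,5).
#' @param beta_rl,beta_wm Softmax sensitivities (fixed configuration
#'   constants, default 50; choice stochasticity is carried by the
#'   accumulator race, not the softmax).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha_rl, bias, phi, rho, capacity,
                         beta_rl = 50, beta_wm = 50) {
  chk01 <- function(x, nm) if (!is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must lie strictly in (0,1)", nm))
  chk01(alpha_rl, "alpha_rl"); chk01(bias, "bias")
  chk01(phi, "phi"); chk01(rho, "rho")
  if (!is.finite(capacity) || capacity <= 2 || capacity >= 5)
    stop("capacity must lie strictly in (2,5)")
  structure(list(alpha_rl = alpha_rl, bias = bias, phi = phi, rho = rho,
                 capacity = capacity, alpha_wm = 1,
                 beta_rl = beta_rl, beta_wm = beta_wm),
            class = "agent_params")
}

#' Initial agent state for one block
#'
#' Both Q matrices start at the uninformed value `1/n_actions`.
#'
#' @param n_stimuli Set size of the block.
#' @param params An [agent_params()] object (supplies the mixing weight).
#' @param n_actions Number of actions (3).
#' @return Object of class `agent_state`: matrices `q_rl`, `q_wm`
#'   (`n_stimuli` x 3) and scalar `w_wm`.
#' @export
agent_state <- function(n_stimuli, params, n_actions = 3L) {
  q0 <- matrix(1 / n_actions, nrow = n_stimuli, ncol = n_actions)
  structure(list(q_rl = q0, q_wm = q0,
                 w_wm = mixing_weight(params$rho, params$capacity, n_stimuli),
                 n_actions = as.integer(n_actions)),
            class = "agent_state")
}

#' Delta-rule update with negative-feedback bias (RL module)
#'
#' `q' = q + a_eff * (r - q)` with `a_eff = alpha_rl` for non-negative
#' prediction errors and `(1 - bias) * alpha_rl` for negative ones.
#'
#' @param q Current expected reward, in \[0,1\].
#' @param reward Observed reward, 0 or 1.
#' @param params [agent_params()].
#' @return Updated value.
#' @export
rl_update <- function(q, reward, params) {
  a <- ifelse(reward - q >= 0, params$alpha_rl,
              (1 - params$bias) * params$alpha_rl)
  q + a * (reward - q)
}

#' One-shot delta-rule update with negative-feedback bias (WM module)
#'
#' As [rl_update()] but with learning rate 1: positive feedback sets the value
#' to the reward exactly; negative feedback moves it by `1 - bias` of the way.
#'
#' @inheritParams rl_update
#' @return Updated value.
#' @export
wm_update <- function(q, reward, params) {
  a <- ifelse(reward - q >= 0, 1, 1 - params$bias)
  q + a * (reward - q)
}

#' Decay all WM values toward their initial value
#'
#' Applied once per trial to every stimulus-action entry:
#' `q' = q + phi * (1/3 - q)`.
#'
#' @param state An [agent_state()].
#' @param params [agent_params()].
#' @return The state with decayed `q_wm`.
#' @export
wm_decay <- function(state, params) {
  q0 <- 1 / state$n_actions
  state$q_wm <- state$q_wm + params$phi * (q0 - state$q_wm)
  state
}

#' Working-memory mixing weight
#'
#' `W_WM = rho * min(1, C / n_s)`: WM informs choice fully when capacity
#' covers the set size and proportionally less when it does not.
#'
#' @param rho Propensity to use WM.
#' @param capacity WM capacity C.
#' @param set_size Number of stimulus-response associations in the block.
#' @return Mixing weight in \[0,1\].
#' @export
mixing_weight <- function(rho, capacity, set_size) {
  if (any(set_size <= 0)) stop("set_size must be positive")
  rho * pmin(1, capacity / set_size)
}

# Overflow-safe softmax of beta * q over actions (rows of a matrix or a vector)
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

#' Action policy for one stimulus
#'
#' Softmax policies of each module, mixed by the WM weight:
#' `pi = W_WM * p_wm + (1 - W_WM) * p_rl`.
#'
#' @param state [agent_state()].
#' @param stimulus Row index of the stimulus in the state's Q matrices.
#' @param params [agent_params()].
#' @return List with probability 3-vectors `p_rl`, `p_wm`, `pi`.
#' @export
policy <- function(state, stimulus, params) {
  if (stimulus < 1 || stimulus > nrow(state$q_rl)) stop("unknown stimulus")
  p_rl <- softmax(params$beta_rl * state$q_rl[stimulus, ])
  p_wm <- softmax(params$beta_wm * state$q_wm[stimulus, ])
  pi <- state$w_wm * p_wm + (1 - state$w_wm) * p_rl
  list(p_rl = p_rl, p_wm = p_wm, pi = pi)
}

# Policies for all stimuli at once: returns an n_s x 3 matrix of mixed pi.
policy_matrix <- function(state, params) {
  p_rl <- softmax(params$beta_rl * state$q_rl)
  p_wm <- softmax(params$beta_wm * state$q_wm)
  state$w_wm * p_wm + (1 - state$w_wm) * p_rl
}

#' Shannon entropy of the block-average policy
#'
#' Before the trial's stimulus is encoded, the agent's uncertainty about the
#' stimulus-response mappings is summarized by averaging the mixed policy over
#' the block's stimuli, `mu_i = mean_s pi(a_i | s)`, and taking its Shannon
#' entropy in bits, `H = -sum_i mu_i log2 mu_i` (with `0 log2 0 := 0`). The
#' value is floored at `eps` to keep downstream drift rates finite.
#'
#' @param state [agent_state()] holding all the block's stimuli.
#' @param params [agent_params()].
#' @param eps Lower floor in bits (default `1e-6`).
#' @return Entropy in bits, in `[eps, log2(3)]`.
#' @export
prior_entropy <- function(state, params, eps = 1e-6) {
  mu <- colMeans(policy_matrix(state, params))
  h <- -sum(ifelse(mu > 0, mu * log2(mu), 0))
  max(h, eps)
}
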