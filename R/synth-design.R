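#' Specification of a synthetic orienting experiment
#'
#' Encodes the design constants of the two-alternative saccadic orienting
#' task: a jittered central fixation period, simultaneous presentation of a
#' fearful and a neutral face at opposite horizontal eccentricities, and a
#' blocked Instruction (Yield / Oppose) by Disruption (none / stimulation)
#' manipulation. Disruption laterality (ipsilateral / contralateral to the
#' fearful face) is a trial-level label induced by the randomized fearful-face
#' hemifield and the participant's fixed electrode side.
#'
#' @param n_participants number of participants.
#' @param blocks_per_condition blocks per Instruction x Disruption-presence
#'   condition per participant.
#' @param trials_per_block trials per block (default 50).
#' @param fixation_ms central fixation duration (default 1750 ms).
#' @param jitter_ms half-range of the uniform fixation jitter (default 250 ms).
#' @param eccentricity_deg horizontal face eccentricity (default 5.3 deg).
#' @param presentation_ms face presentation duration (default 1000 ms).
#' @param instruction_levels,disruption_levels,hemifield_levels factor level
#'   sets; the defaults are the analysable labels.
#' @param seed master seed; all trial-level randomization is derived from it
#'   through counter-based substreams.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_participants = 6, blocks_per_condition = 1,
                        trials_per_block = 50, fixation_ms = 1750,
                        jitter_ms = 250, eccentricity_deg = 5.3,
                        presentation_ms = 1000,
                        instruction_levels = c("Yield", "Oppose"),
                        disruption_levels = c("None", "Ipsi", "Contra"),
                        hemifield_levels = c("L", "R"),
                        seed = 1L) {
  if (!is.numeric(trials_per_block) || trials_per_block <= 0)
    stop("trials_per_block must be > 0")
  if (!is.numeric(n_participants) || n_participants <= 0)
    stop("n_participants must be > 0")
  if (!is.numeric(blocks_per_condition) || blocks_per_condition <= 0)
    stop("blocks_per_condition must be > 0")
  if (jitter_ms < 0) stop("jitter_ms must be >= 0")
  if (!identical(sort(instruction_levels), sort(c("Yield", "Oppose"))))
    stop("instruction_levels must be {Yield, Oppose}")
  if (!all(c("None") %in% disruption_levels) || length(disruption_levels) != 3)
    stop("disruption_levels must be None plus two laterality labels")
  if (length(hemifield_levels) != 2)
    stop("hemifield_levels must have two levels")
  structure(list(
    n_participants = as.integer(n_participants),
    blocks_per_condition = as.integer(blocks_per_condition),
    trials_per_block = as.integer(trials_per_block),
    fixation_ms = fixation_ms, jitter_ms = jitter_ms,
    eccentricity_deg = eccentricity_deg, presentation_ms = presentation_ms,
    instruction_levels = instruction_levels,
    disruption_levels = disruption_levels,
    hemifield_levels = hemifield_levels,
    seed = as.integer(seed)), class = "design_spec")
}

#' Expand a design specification into a trial list
#'
#' Generates the full factorial block structure and per-trial randomization:
#' the fearful-face hemifield is assigned uniformly at random per trial and
#' fixation durations are jittered uniformly within the stated half-range.
#' The result is deterministic given the spec's seed, and each trial's draws
#' come from its own counter-based substream.
#'
#' @param spec a [design_spec()].
#' @return A data.frame with one row per trial: participant, electrode side,
#'   block, trial, instruction, disruption presence and trial-level laterality
#'   label, fearful-face hemifield, fixation duration, and the trial's RNG
#'   substream seed.
#' @export
make_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  lat_levels <- setdiff(spec$disruption_levels, "None") # c("Ipsi", "Contra")
  conds <- expand.grid(instruction = spec$instruction_levels,
                       disrupted = c(FALSE, TRUE),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- conds[rep(seq_len(nrow(conds)), each = spec$blocks_per_condition), ,
                  drop = FALSE]
  n_blocks <- nrow(blocks)
  n_per_subj <- n_blocks * spec$trials_per_block

  out <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    electrode <- spec$hemifield_levels[1 + (p - 1) %% 2]
    df <- data.frame(
      participant = p,
      electrode_side = electrode,
      block = rep(seq_len(n_blocks), each = spec$trials_per_block),
      trial = rep(seq_len(spec$trials_per_block), n_blocks),
      instruction = rep(blocks$instruction, each = spec$trials_per_block),
      disrupted = rep(blocks$disrupted, each = spec$trials_per_block),
      stringsAsFactors = FALSE)
    counter0 <- (p - 1) * n_per_subj
    df$seed_trial <- substream_seeds(spec$seed, counter0 + seq_len(n_per_subj))
    # per-trial randomization from the trial substream
    rnd <- vapply(df$seed_trial, function(s) with_seed(s, c(
      runif(1), runif(1))), numeric(2))
    df$hemifield_fear <- spec$hemifield_levels[1 + (rnd[1, ] < 0.5)]
    df$fixation_ms <- spec$fixation_ms + (2 * rnd[2, ] - 1) * spec$jitter_ms
    df$disruption <- ifelse(!df$disrupted, "None",
                            ifelse(df$hemifield_fear == df$electrode_side,
                                   lat_levels[1], lat_levels[2]))
    out[[p]] <- df
  }
  design <- do.call(rbind, out)
  rownames(design) <- NULL
  # persistent per-trial counter: substreams attach to it, so subsetting a
  # design never shifts another trial's draws
  design$trial_uid <- seq_len(nrow(design))
  attr(design, "spec") <- spec
  design
}
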