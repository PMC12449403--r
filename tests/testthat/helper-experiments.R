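# Shared experiment configurations.
#
# The epoch experiments place the deterioration ~4 days into a ~10 day
# stay so the whole 36-hour pre-deterioration horizon lies inside the
# admission window: the three 12-hour windows are then exchangeable under
# a multiplier of 1 (a true null) and differ only through the planted
# escalation ramp otherwise.
epoch_experiment_config <- function(seed, multiplier,
                                    n_encounters = 100L,
                                    los_log_mean = log(10),
                                    los_log_sd = 0.25,
                                    det_time_log_median = 4,
                                    det_time_log_sd = 0.25) {
  sim_config(n_total_encounters = as.integer(n_encounters),
             p_message_linked_encounter = 1,
             p_deterioration = 1,
             escalation_multiplier = multiplier,
             los_log_mean = los_log_mean, los_log_sd = los_log_sd,
             det_time_log_median = det_time_log_median,
             det_time_log_sd = det_time_log_sd,
             seed = seed)
}

# leaner variant for replicated null runs (shorter stays, deterioration
# ~2.5 days in, still covering the 36 h horizon)
epoch_null_config <- function(seed) {
  epoch_experiment_config(seed, multiplier = 1, n_encounters = 40L,
                          los_log_mean = log(5), los_log_sd = 0.15,
                          det_time_log_median = 2.5,
                          det_time_log_sd = 0.15)
}
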