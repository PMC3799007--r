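# independent hand simulation of the update rules for an observer whose
# responses are all correct or all wrong
oracle_trace <- function(n_trials, all_correct) {
  ladder <- duration_ladder()
  level <- 1L; idx <- 3L
  pre <- data.frame(level = integer(n_trials), duration = numeric(n_trials),
                    post_level = integer(n_trials), post_duration = numeric(n_trials))
  for (i in seq_len(n_trials)) {
    pre$level[i] <- level; pre$duration[i] <- ladder[idx]
    if (i %% 4 == 0) {
      if (all_correct) {                       # 100% > 75%: harder
        if (idx < length(ladder)) idx <- idx + 1L
        else if (level < 4L) level <- level + 1L
      } else {                                 # 0% < 37.5%: easier
        if (idx > 1L) idx <- idx - 1L
        else if (level > 1L) level <- level - 1L
      }
    }
    pre$post_level[i] <- level; pre$post_duration[i] <- ladder[idx]
  }
  pre
}
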