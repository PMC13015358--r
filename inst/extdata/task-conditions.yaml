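# Task parameters for the three study cohorts, one entry per block.
# Step means/stds are in normalized screen units (screen edge = 1,
# seed piles = +/-0.8). mean_magnitudes lists one value for fixed-SNR
# blocks and two (in order) for trial-mixed and changepoint blocks.
blocks:
  - {cohort: 1, block: 1, mean_magnitudes: [0.05], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 0}
  - {cohort: 1, block: 2, mean_magnitudes: [0.05], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: -4, steps_error_penalty: 0}
  - {cohort: 1, block: 3, mean_magnitudes: [0.05], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 30}
  - {cohort: 1, block: 4, mean_magnitudes: [0.15], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 0}
  - {cohort: 1, block: 5, mean_magnitudes: [0.15], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: -4, steps_error_penalty: 0}
  - {cohort: 1, block: 6, mean_magnitudes: [0.15], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 30}
  - {cohort: 2, block: 1, mean_magnitudes: [0.05, 0.15], step_std: 0.15, snr_mode: trial_mixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 0}
  - {cohort: 2, block: 2, mean_magnitudes: [0.05, 0.15], step_std: 0.15, snr_mode: trial_mixed, coins_correct: 1, coins_error: -4, steps_error_penalty: 0}
  - {cohort: 2, block: 3, mean_magnitudes: [0.05, 0.15], step_std: 0.15, snr_mode: trial_mixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 30}
  - {cohort: 2, block: 4, mean_magnitudes: [0.1], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 0}
  - {cohort: 2, block: 5, mean_magnitudes: [0.1], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: -4, steps_error_penalty: 0}
  - {cohort: 2, block: 6, mean_magnitudes: [0.1], step_std: 0.15, snr_mode: fixed, coins_correct: 1, coins_error: 0, steps_error_penalty: 30}
  - {cohort: 3, block: 1, mean_magnitudes: [0.01], step_std: 0.05, snr_mode: fixed, coins_correct: 1, coins_error: -1, steps_error_penalty: 0}
  - {cohort: 3, block: 2, mean_magnitudes: [0.02], step_std: 0.05, snr_mode: fixed, coins_correct: 1, coins_error: -1, steps_error_penalty: 0}
  - {cohort: 3, block: 3, mean_magnitudes: [0.01, 0.02], step_std: 0.05, snr_mode: trial_mixed, coins_correct: 1, coins_error: -1, steps_error_penalty: 0}
  - {cohort: 3, block: 4, mean_magnitudes: [0.01, 0.02], step_std: 0.05, snr_mode: changepoint, coins_correct: 1, coins_error: -1, steps_error_penalty: 0}
  - {cohort: 3, block: 5, mean_magnitudes: [0.02, 0.01], step_std: 0.05, snr_mode: changepoint, coins_correct: 1, coins_error: -1, steps_error_penalty: 0}
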