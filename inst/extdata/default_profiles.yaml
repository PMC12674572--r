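# Synthetic activity-condition profiles (emulation).
#
# A default set of 12 conditions spanning the eight superordinate activity
# categories, standing in for a full 32-condition laboratory protocol whose
# exact listing is not shipped here. Users can extend this file to any
# number of conditions; each entry defines, per wearing location, the
# posture-dependent gravity orientation (unit 3-vector, g), the periodic
# movement amplitude (mg), and shares a fundamental frequency (Hz),
# harmonic weights and white-noise SD (mg per axis).
#
# Amplitudes were chosen once so that category orderings and placement
# effects of real recordings hold by construction (e.g. wrist > thigh for
# household activity, ankle/thigh > wrist for cycling); they are not fitted
# to any measured values.
conditions:
  - id: lying_horizontal
    category: lying
    duration_s: 180
    fundamental_hz: 0.3
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 0, hip: 0, chest: 0, ankle: 0, wrist: 0, upper_arm: 0}
    gravity:
      thigh: [1, 0, 0]
      hip: [1, 0, 0]
      chest: [1, 0, 0]
      ankle: [1, 0, 0]
      wrist: [1, 0, 0]
      upper_arm: [1, 0, 0]
  - id: sitting_leaned_backwards
    category: sitting
    duration_s: 180
    fundamental_hz: 0.4
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 8, hip: 6, chest: 12, ankle: 8, wrist: 24, upper_arm: 16}
    gravity:
      thigh: [1, 0, 0]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: sitting_upright
    category: sitting
    duration_s: 150
    fundamental_hz: 0.4
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 12, hip: 9, chest: 16, ankle: 12, wrist: 34, upper_arm: 22}
    gravity:
      thigh: [1, 0, 0]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: standing
    category: standing
    duration_s: 150
    fundamental_hz: 0.5
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 35, hip: 45, chest: 70, ankle: 25, wrist: 380, upper_arm: 200}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: tidying_up
    category: adl
    duration_s: 240
    fundamental_hz: 0.8
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 110, hip: 90, chest: 100, ankle: 170, wrist: 320, upper_arm: 180}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: hanging_out_laundry
    category: adl
    duration_s: 240
    fundamental_hz: 0.8
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 130, hip: 110, chest: 120, ankle: 200, wrist: 380, upper_arm: 220}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: climbing_stairs
    category: climbing_stairs
    duration_s: 150
    fundamental_hz: 1.6
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 750, hip: 620, chest: 640, ankle: 1250, wrist: 620, upper_arm: 600}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: walking_3.2kmh
    category: walking
    duration_s: 300
    fundamental_hz: 1.5
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 600, hip: 400, chest: 360, ankle: 1050, wrist: 350, upper_arm: 310}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: walking_5.5kmh
    category: walking
    duration_s: 240
    fundamental_hz: 1.9
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 820, hip: 550, chest: 500, ankle: 1400, wrist: 480, upper_arm: 420}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: jogging_8kmh
    category: jogging
    duration_s: 180
    fundamental_hz: 2.5
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 1900, hip: 1700, chest: 1800, ankle: 2450, wrist: 2050, upper_arm: 1650}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: jogging_10kmh
    category: jogging
    duration_s: 150
    fundamental_hz: 2.8
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 2100, hip: 1900, chest: 2000, ankle: 2750, wrist: 2350, upper_arm: 1850}
    gravity:
      thigh: [0, 0, 1]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0, 0, 1]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
  - id: cycling
    category: cycling
    duration_s: 300
    fundamental_hz: 1.4
    harmonics: {"1": 1.0, "2": 0.4}
    noise_sd_mg: 8
    amplitude_mg: {thigh: 400, hip: 170, chest: 160, ankle: 640, wrist: 250, upper_arm: 260}
    gravity:
      thigh: [0.70710678, 0, 0.70710678]
      hip: [0, 0, 1]
      chest: [0, 0, 1]
      ankle: [0.70710678, 0, 0.70710678]
      wrist: [0, 0, 1]
      upper_arm: [0, 0, 1]
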