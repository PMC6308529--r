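Package: gaitinfer
Title: Gait Inference and Intention Recognition from Thigh-Worn Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlling lower-limb prostheses from thigh-mounted
    inertial and electromyography (EMG) sensors. Reads tab-separated
    wearable-sensor recordings (accelerometer, gyroscope, EMG), derives
    sagittal-plane thigh and shank angles by gravity-referenced tilt plus
    gyroscope integration, predicts the shank angles of missing lower legs
    from thigh motion with a long short-term memory (LSTM) recurrent network
    trained on short sequence chunks, recognizes sitting/standing/moving
    states and EMG-signalled stand-up/sit-down intentions with a low-latency
    context-window classifier built on Gaussian mixture emissions fitted by
    expectation-maximization, and drives a prosthesis controller state
    machine. Includes a synthetic gait and EMG generator with ground truth
    and a leave-one-subject-out evaluation harness reporting degree errors
    (overall, per activity, per gait phase, around activity transitions),
    precision/recall/F1, and detection latency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
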