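Package: auriscale
Title: Auditory Receptive Fields from Temporal Scale-Space Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Idealized auditory receptive fields built on temporal scale-space
    theory. Provides time-causal (truncated-exponential cascade) and non-causal
    (Gaussian) temporal smoothing kernels and their scale discretizations,
    multi-scale spectrograms equivalent to Gabor, Gammatone and generalized
    Gammatone filter banks with wavelength-proportional window scales, a second
    layer of separable and glissando-adapted spectro-temporal receptive fields
    over a log-frequency/log-magnitude spectrogram, derived auditory feature
    operators (onset/offset detection, spectral-band enhancement, partial-tone
    ridge curves, glissando estimation), and analytical characterization of the
    frequency selectivity and temporal dynamics of the window families.
    Includes synthetic stimulus generation and WAV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
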