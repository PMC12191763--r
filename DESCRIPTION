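Package: cheap
Title: Compressed Hourglass Embedding Adaptations of Protein Language
    Model Latents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Neural compression of per-residue protein language model
    latents. Provides per-channel min-max normalization that corrects
    massive activations (a small set of input-independent outlier
    channels with extreme magnitudes), the hourglass protein compression
    transformer (HPCT) -- an autoencoder that shortens embeddings
    lengthwise by linear downsampling and narrows them channelwise by a
    linear projection around a continuous (tanh) or discrete (VQ-VAE or
    finite scalar quantization) bottleneck -- together with masked-MSE
    training, a per-residue sequence decoder head, linear probes,
    structure reconstruction metrics (RMSD with Kabsch superposition,
    superposition-free RMSPD, TM-score), and latent-space experiments
    (linear interpolation, token corruption). A seeded synthetic
    generator reproduces the statistical pathologies of real latents so
    the full stack is testable without external model inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    Biostrings,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
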