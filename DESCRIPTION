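Package: cgnoise
Title: Coarse-Grained Force Fields from Forces and Denoising Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Trains bottom-up coarse-grained (CG) force fields by combining
    variational force matching with single-noise-level denoising score
    matching through a Gaussian noise kernel that replaces the deterministic
    CG map probabilistically. Provides statistically optimal linear force
    maps (constrained ridge least squares for the atomistic stage, a
    post-map noise stage), synthetic fine-grained reference systems with
    analytic or quadrature ground-truth potentials of mean force, BAOAB
    Langevin and parallel-tempering CG simulators, and free-energy-surface
    analysis tools (histogram FES, FES error metrics, TICA, native
    contacts). All energies are handled in thermal units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
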