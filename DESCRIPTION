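Package: pcmorph
Title: Livestock Body Morphometry from Multiview Point Clouds
Version: 0.1.0
Authors@R:
    person("Point Cloud Morphometry", "Contributors",
           email = "pcmorph@example.com", role = c("aut", "cre"))
Description: Measures body parameters of live animals (pigs, cattle, sheep)
    from multiview depth-camera point clouds. Provides readers and writers
    for PLY/PCD/XYZ clouds, passthrough cropping, RANSAC ground-plane
    removal and statistical outlier filtering, coarse registration by
    4-point congruent sets with affine-invariant intersection ratios,
    iterative-closest-point refinement, repair of occlusion holes by
    slice-projected uniform cubic B-spline fitting, anatomical key-point
    detection on silhouette ranges, symmetry-plane mirroring of half-body
    captures, and computation of six body parameters (diagonal and
    horizontal length, shoulder and abdominal width, height, chest depth)
    plus chest circumference. Includes a ground-truthed synthetic quadruped
    generator so every stage is testable without captured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
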