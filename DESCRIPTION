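Package: kneeCDI
Title: Cartilage Damage Index Quantification from Knee MRI Slice Contours
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies medial tibiofemoral cartilage damage from sagittal
    knee MR slice contours via the Cartilage Damage Index (CDI): a
    rectangular universal (u,v) coordinate system is laid over each
    articular surface, cartilage thickness and anterior-posterior cartilage
    length are measured at a small set of informative locations, and their
    products with the slice thickness are summed into a per-bone volume
    proxy. Includes the discovery procedure that selects informative
    locations from denuded-cartilage frequency maps, a phantom simulator
    with known ground-truth thickness fields for validation without image
    data, and the reliability and construct-validity statistics used to
    evaluate such imaging biomarkers (ICC(2,1), ICC(3,1), standardized
    response mean, Spearman correlation, linear trend over ordinal grade).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'thickness.R'
    'cdi.R'
    'discovery.R'
    'phantom.R'
    'io.R'
    'conditions.R'
    'reliability.R'
    'validation.R'
    'cli.R'
    'kneeCDI-package.R'
    'utils-polyline.R'
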