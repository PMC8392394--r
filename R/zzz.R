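.onLoad <- function(libname, pkgname) {
  # manifest sanity: the feature space is frozen at 193 columns
  stopifnot(sum(FEATURE_BLOCK_SIZES) == 193L,
            length(featureManifest()$names) == 193L,
            !anyDuplicated(featureManifest()$names))
}
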