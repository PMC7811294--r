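# shared fixtures: published parameter sets and a small noiseless dataset

caf_pars <- published_params("caf")
cc_pars <- published_params("cc")
co_merged <- published_params("coculture_merged")
co_stress <- published_params("coculture_stress")

# noiseless CAF design dataset at the published values (computed once;
# several tests reuse it)
caf_noiseless <- generate_data(design_spec("CAF", noise = 0), caf_pars)

# memoized store for expensive fits shared between test files
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fit_cache)) assign(key, force(expr), .fit_cache)
  get(key, .fit_cache)
}
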