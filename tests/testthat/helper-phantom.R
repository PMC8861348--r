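# Shared small phantom configurations. The reduced grid (28 x 44 x 44 at
# 5 mm) keeps registration and dose tests fast while preserving all
# anatomy; heavy objects are cached once per test run.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(28L, 44L, 44L), spacing = c(5, 5, 5), ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_case <- function() cached("small_case", generate_phantom(small_spec(), 1))

noiseless_case <- function() {
  cached("noiseless_case",
         generate_phantom(small_spec(noise_sd = c(ct = 0, mri = 0),
                                     bias_field_amplitude = 0), 2))
}

# unit-scale water-channel intensity + guidance masks, the registration input
reg_input <- function(case, bias_correct = TRUE) {
  ch <- case$mri$water
  if (bias_correct) ch <- correct_bias_field(ch, case$masks$body)
  a <- unclass(ch)
  attributes(a) <- list(dim = dim(a))
  list(intensity = a / median(a[case$masks$body]),
       masks = case$masks[c("body", "bone", "bladder")])
}

vol_data <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(a))
  a
}
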