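# One shared end-to-end run of the default synthetic study (1 Mb, 3
# individuals x 9 tissues), reused by every test that asserts on it.
.default_run_cache <- new.env(parent = emptyenv())

get_default_run <- function() {
  if (!exists("res", envir = .default_run_cache)) {
    d <- file.path(tempdir(), "rnaeditome-default-study")
    st <- simulate_study(synthetic_config(), file.path(d, "study"))
    res <- run_pipeline(file.path(d, "study"), file.path(d, "out"),
                        verbose = FALSE)
    assign("st", st, envir = .default_run_cache)
    assign("res", res, envir = .default_run_cache)
  }
  list(st = get("st", envir = .default_run_cache),
       res = get("res", envir = .default_run_cache))
}
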