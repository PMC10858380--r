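# Shared small rendered cohort, built once per test run and copied into a
# fresh directory for each test so mutating tests cannot interfere.
.cohort_cache <- new.env(parent = emptyenv())

local_cohort_dir <- function(n = 20, seed = 5, env = parent.frame()) {
  if (is.null(.cohort_cache$dir)) {
    .cohort_cache$dir <- file.path(tempdir(), "lesiondist-cohort-cache")
    co <- simulate_cohort(cohort_spec(n_patients = n, seed = seed),
                          render = TRUE)
    write_cohort(co, .cohort_cache$dir)
  }
  dir <- withr::local_tempdir(.local_envir = env)
  file.copy(list.files(.cohort_cache$dir, full.names = TRUE), dir)
  # manifest paths point at the cache; rewrite them to the copy
  man <- read.csv(file.path(dir, "manifest.csv"))
  for (cc in c("lesion_mask", "organ_mask"))
    man[[cc]] <- file.path(dir, basename(man[[cc]]))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  dir
}
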