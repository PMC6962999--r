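# campaign fixtures are expensive; build each once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

small_campaign <- function() {
  cached_fixture("small_campaign", function() {
    generate_campaign(campaign_config(n_days = 2, scans_per_day = 6,
                                      seed = 11L))
  })
}

# the default demonstration campaign run end to end (2 genotypes x 4 plots
# x 14 days, hourly scans)
demo_run <- function() {
  cached_fixture("demo_run", function() {
    run_pipeline(campaign_config(),
                 out_dir = file.path(tempdir(), "liftkin-demo-run"))
  })
}
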