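# small fixtures built in code

toy_table <- function() {
  otu_table(matrix(c(5L, 3L, 0L,
                     1L, 0L, 2L,
                     0L, 4L, 4L,
                     2L, 2L, 2L), 4, 3, byrow = TRUE,
                   dimnames = list(paste0("otu", 1:4), paste0("s", 1:3))))
}

# two stations per habitat, two dates, duplicate filters
toy_design <- function(n_dates = 2L) {
  stations <- c("StA1", "StA2", "StB1", "StB2")
  habitat <- c("A", "A", "B", "B")
  dates <- paste0("d", seq_len(n_dates))
  df <- expand.grid(replicate = 1:2, station = stations, date = dates,
                    stringsAsFactors = FALSE)
  df$habitat <- habitat[match(df$station, stations)]
  df$sample_id <- paste(df$station, df$date, df$replicate, sep = "_")
  sample_metadata(df[, c("sample_id", "station", "habitat", "date",
                         "replicate")])
}

toy_counts_for <- function(meta, n_otus = 12L, seed = 3L, lambda = 40) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * nrow(meta), lambda), n_otus, nrow(meta),
              dimnames = list(sprintf("otu%02d", seq_len(n_otus)),
                              meta$sample_id))
  otu_table(m)
}

# compact generator settings for fast end-to-end tests
test_synth_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_otus = 80L, depth_mean = 2500, seed = 101L,
                   association_blocks = list(
                     list(habitat = "A", size = 6L, strength = 0.9),
                     list(habitat = "B", size = 6L, strength = 0.9)))
  defaults[names(args)] <- args
  do.call(synthetic_config, defaults)
}
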