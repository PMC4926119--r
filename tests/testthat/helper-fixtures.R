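# Shared fixtures, built once per test run and memoised. All seeds fixed.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# small transcriptome with planted hairpins (cheap; used by many files)
fx_planted <- function() {
  memo("planted", function() {
    tr <- make_transcriptome(40, c(400, 1500), gc = 0.56, seed = 11)
    c(plant_hairpins(tr, 10, seed = 12), list(base = tr))
  })
}

# the default four-library study preset, simulated, cleaned and classified
fx_pipeline <- function() {
  memo("pipeline", function() {
    ph <- fx_planted()
    refs <- make_reference_sets(seed = 13)
    dir <- file.path(tempdir(), "mirweed-fixture")
    fq <- simulate_libraries(ph$truth, ph$transcripts, refs,
                             default_library_specs(n_reads = 1e5, seed = 14),
                             dir = dir)
    cl <- lapply(seq_len(nrow(fq)), function(i) {
      clean_library(fq$path[i], library = fq$library[i])
    })
    stats <- dplyr::bind_rows(lapply(cl, `[[`, "stats"))
    long <- dplyr::bind_rows(lapply(cl, function(x) {
      tibble::tibble(library = x$stats$library, sequence = x$tags$sequence)
    }))
    tags <- collapse_unique(long)
    ann <- classify_tags(tags, refs)
    truth_class <- dplyr::bind_rows(lapply(cl, function(x) {
      f <- x$fates
      f$planted <- sub("^[^|]+\\|[^|]+\\|([^|]+)\\|.*$", "\\1", f$name)
      f$library <- x$stats$library
      f
    }))
    list(ph = ph, refs = refs, fq = fq, cl = cl, stats = stats,
         tags = tags, ann = ann, truth_class = truth_class)
  })
}

# unannotated tags from the pipeline fixture
fx_unannotated <- function() {
  ann <- fx_pipeline()$ann
  out <- ann$assignments[ann$assignments$category == "unannotated", ]
  out[, setdiff(names(out), c("category", "ref_name", "mismatches"))]
}

random_rna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), len, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
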