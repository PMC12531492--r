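# Locating genome-scale reconstructions for the paper-number checks.  The
# models are several MB and are not shipped with the package; they are
# looked up in a local cache and, failing that, fetched from the BiGG model
# repository.  Returns NULL when unavailable.

genome_model_path <- function(id, url = NULL) {
  candidates <- c(
    file.path(Sys.getenv("HOME"), ".cache", "adaptuc", paste0(id, ".json")),
    testthat::test_path("..", "..", "scratch", "models", paste0(id, ".json")),
    file.path(tempdir(), paste0(id, ".json")))
  for (p in candidates) if (file.exists(p) && file.size(p) > 1e5) return(p)
  if (is.null(url)) url <- paste0("http://bigg.ucsd.edu/static/models/",
                                  id, ".json")
  dest <- file.path(tempdir(), paste0(id, ".json"))
  ok <- tryCatch({
    suppressWarnings(utils::download.file(url, dest, quiet = TRUE,
                                          method = "libcurl"))
    file.exists(dest) && file.size(dest) > 1e5
  }, error = function(e) FALSE)
  if (isTRUE(ok)) dest else NULL
}
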