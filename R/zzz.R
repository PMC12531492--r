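.onLoad <- function(libname, pkgname) {
  # Point reticulate at the environment python before it initialises, unless
  # the user has already pinned one.
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
  invisible()
}
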