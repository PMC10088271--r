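withr_local_tempfile <- function(ext = "") {
  withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
}
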