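.onLoad <- function(libname, pkgname) {
  # keep the Open Babel backend from spamming stderr with per-molecule
  # stereo warnings; real errors still surface
  try({
    ns <- asNamespace("ChemmineOB")
    if (all(c("obErrorLog_get", "OBMessageHandler_SetOutputLevel",
              "obMessageLevel_obError_get") %in% ls(ns))) {
      log <- ns$obErrorLog_get()
      ns$OBMessageHandler_SetOutputLevel(log, ns$obMessageLevel_obError_get())
    }
  }, silent = TRUE)
  invisible()
}
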