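# Structured error conditions so the command-line wrapper can map failures to
# distinct exit codes (config -> 2, data -> 3, numerical -> 4).

configError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("qdabiplot_config_error", "qdabiplot_error")))
}

dataError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("qdabiplot_data_error", "qdabiplot_error")))
}

numericalError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("qdabiplot_numerical_error", "qdabiplot_error")))
}

stageLog <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  details <- paste(
    vapply(list(...), function(x) paste(format(x), collapse = ","),
           character(1)),
    collapse = " ")
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%OS2"),
                  stage, details))
  invisible(NULL)
}
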