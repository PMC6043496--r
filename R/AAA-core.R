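# Core constants and condition helpers, sourced before everything else.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

userError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("disoPPI_user_error", "disoPPI_error")))
}

configError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("disoPPI_config_error", "disoPPI_error")))
}
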