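# Shared builders for tests. The bundled study dataset is loaded once;
# small toy objects are constructed in code.

fx <- load_crc_fixture()

toy_components <- function(amounts = c(a = 10, b = 4), se = NA_real_) {
  cost_components(names(amounts), "recurrent", "activity_based",
                  unname(amounts), se)
}

toy_stage_table <- function(arm = "iFOBT", s = c(2, 2, 2, 2),
                            n = c(1, 1, 1, 1), u = c(1, 1, 1, 1),
                            tc = NA_real_) {
  stage_table(arm, c("I", "II", "III", "IV"), s, n, u, tc)
}

# random valid stage table for property-style loops
random_stage_table <- function() {
  toy_stage_table(s = stats::runif(4, 0, 10),
                  n = sample(0:50, 4, replace = TRUE) + c(1, 0, 0, 0),
                  u = stats::runif(4, 0, 1))
}
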