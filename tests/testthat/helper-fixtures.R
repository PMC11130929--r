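# Shared fixtures, built once per test run. Surveys are EMIS-sized so the
# scenario proportions and reconstruction targets are exercised at the scale
# they are defined for; smaller ad-hoc surveys are built inline where size
# does not matter.
.fx <- new.env(parent = emptyenv())

fx_survey <- function(scenario = "prep_eligibility") {
  key <- paste0("survey_", scenario)
  if (is.null(.fx[[key]])) {
    cfg <- generator_config(n_respondents = 2763, scenario = scenario)
    .fx[[key]] <- generate_survey(cfg, seed = 11)
  }
  .fx[[key]]
}

fx_recon <- function(scenario = "prep_eligibility") {
  key <- paste0("recon_", scenario)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- reconstruct_survey(fx_survey(scenario), seed = 12)
  .fx[[key]]
}

# a small survey data frame with explicit categories (no generator involved)
make_cat_survey <- function(steady, casual) {
  data.frame(respondent_id = seq_along(steady),
             steady_count_category = as.character(steady),
             casual_count_category = as.character(casual),
             stringsAsFactors = FALSE)
}

# small three-layer model setup used across network tests
fx_model <- function(n = 1000, ha = 0.346,
                     durations = list(steady = 1200, casual_hh = 5,
                                      casual_ll = 250, casual_hl = 10,
                                      oneoff = 1),
                     h = c(steady = 0.8, casual = 0.65, oneoff = 0.98),
                     ...) {
  pop <- population(n, ha)
  deg <- list(steady = c(ha = 0.45, la = 0.30),
              casual = c(ha = 0.80, la = 0.28),
              oneoff = c(ha = 25 / 365, la = 4 / 365))
  n_la <- pop$n - pop$n_ha
  edges <- lapply(deg, function(d)
    (pop$n_ha * d[["ha"]] + n_la * d[["la"]]) / 2)
  hl <- lapply(names(deg), function(ly) {
    d <- deg[[ly]]
    c(ha = unname(h[[ly]]),
      la = la_homophily(mixing_inputs(pop$n_ha, n_la, d[["ha"]], d[["la"]],
                                      h[[ly]])))
  })
  names(hl) <- names(deg)
  list(pop = pop, deg = deg, edges = edges,
       params = model_params(durations = durations, homophily = hl,
                             edges = edges, ...))
}
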