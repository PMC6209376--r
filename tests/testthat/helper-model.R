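# shared fixtures: parameters, life tables built in code

base_params <- function(...) {
  p <- amdscreen::amd_parameters()
  overrides <- list(...)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p
}

fixture_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- amdscreen::default_life_table()
    lt
  }
})

# build a life table from a qx vector over ages 0..(length-1) via the CSV loader
make_lt <- function(qx) {
  ages <- seq_along(qx) - 1
  txt <- paste(c("age,qx", paste(ages, qx, sep = ",")), collapse = "\n")
  amdscreen::load_life_table(txt)
}

# qx = 0 until the terminal age (deaths only at the cap)
immortal_lt <- function(max_age = 100) make_lt(c(rep(0, max_age), 1))

# certain death within a year at every age
lethal_lt <- function(max_age = 100) make_lt(rep(1, max_age + 1))

all_strategy_ids <- function() amdscreen::strategy_catalog()$id
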