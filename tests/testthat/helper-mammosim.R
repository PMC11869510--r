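library(data.table)

# small population table for schedule-level tests
make_women <- function(birth_year, risk_class = "average", enrolled = TRUE,
                       death_age = 110) {
  data.table(
    id = seq_along(birth_year),
    birth_year = birth_year,
    birth_date = birth_year + 0.5,
    risk_class = rep_len(risk_class, length(birth_year)),
    other_cause_death_age = rep_len(death_age, length(birth_year)),
    enrolled = rep_len(enrolled, length(birth_year)),
    weight = 1
  )
}

# split a cumulative total into 20 annual integer tallies (2024..2043)
split_years <- function(total, years = 2024:2043) {
  k <- length(years)
  base <- total %/% k
  counts <- rep(base, k)
  counts[seq_len(total - base * k)] <- counts[seq_len(total - base * k)] + 1
  counts
}
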