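# Independent oracles used across the suite. These deliberately avoid the
# package's classification and kappa code paths: components are counted by
# direct symbol comparison against the coding table, and kappa is evaluated
# step by step from its defining sums.

# Brute-force per-code component counter for one odontogram.
oracle_count <- function(odo, dentition) {
  sel <- odo[odontosurvey::dentition_of(odo$tooth) == dentition, ,
             drop = FALSE]
  decayed <- if (dentition == "permanent") c("1", "2") else c("B", "C")
  filled <- if (dentition == "permanent") "3" else "D"
  missing <- if (dentition == "permanent") "4" else "E"
  list(x = sum(sel$crown %in% decayed),
       y = sum(sel$crown %in% filled),
       z = sum(sel$crown %in% missing),
       w = sum(sel$treatment == "6"))
}

oracle_cpo <- function(odo) {
  cc <- oracle_count(odo, "permanent")
  cc$x + cc$y + cc$z + cc$w
}

oracle_ceo <- function(odo) {
  cc <- oracle_count(odo, "deciduous")
  cc$x + cc$y + cc$w
}

# Step-by-step weighted-kappa evaluation from the defining sums.
oracle_kappa <- function(m, scheme) {
  k <- nrow(m)
  n <- sum(m)
  w <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d <- abs(i - j)
    w[i, j] <- switch(scheme,
                      linear = d / (k - 1),
                      quadratic = (d / (k - 1))^2,
                      unweighted = as.numeric(d > 0))
  }
  p <- m / n
  row_m <- rowSums(p); col_m <- colSums(p)
  d_obs <- 0; d_exp <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d_obs <- d_obs + w[i, j] * p[i, j]
    d_exp <- d_exp + w[i, j] * row_m[i] * col_m[j]
  }
  1 - d_obs / d_exp
}

# Random valid odontogram over a mixed or single dentition set.
random_odontogram <- function(teeth = odontosurvey::fdi_teeth("permanent")) {
  dent <- odontosurvey::dentition_of(teeth)
  crown <- vapply(dent, function(d)
    sample(odontosurvey::crown_alphabet(d), 1L), character(1L))
  treatment <- sample(odontosurvey::treatment_alphabet(), length(teeth),
                      replace = TRUE)
  odontosurvey::normalize_odontogram(
    data.frame(tooth = teeth, crown = crown, treatment = treatment,
               stringsAsFactors = FALSE),
    teeth = teeth)
}

# Small fully-generated survey for pipeline tests.
tiny_survey <- function(seed = 42L, n_schools = 3L, students = 20L) {
  odontosurvey::simulate_survey(odontosurvey::simulation_config(
    n_schools = n_schools, students_per_school = students, seed = seed))
}
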