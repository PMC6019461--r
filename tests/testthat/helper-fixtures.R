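# Shared fixtures, built once per test run.

fx <- new.env()

fixture_db <- function() {
  if (is.null(fx$db)) fx$db <- simulate_germline_db(seed = 101)
  fx$db
}

fixture_layout <- function() {
  if (is.null(fx$layout)) fx$layout <- default_layout(fixture_db())
  fx$layout
}

# small 12-clone standard set over 12 distinct V genes
fixture_set <- function() {
  if (is.null(fx$set)) {
    db <- fixture_db()
    plan <- stats::setNames(rep(1L, 12), db$v$name[seq(1, 48, by = 4)])
    fx$set <- design_standard_set(db, fixture_layout(), n_clones = 12,
                                  v_usage_plan = plan, n_shm_standards = 5,
                                  seed = 3)
  }
  fx$set
}

# the full-scale 85-clone reference design (built on demand; cached)
fixture_set85 <- function() {
  if (is.null(fx$set85)) {
    fx$set85 <- design_standard_set(fixture_db(), fixture_layout(),
                                    n_clones = 85, seed = 1)
  }
  fx$set85
}

# minimal annotated-record table for clonotyping tests
make_records <- function(junction_aa, v_gene = "IGHV1-1", j_gene = "IGHJ1",
                         sequence = NULL, shm = 0, rid_count = 1,
                         replicate_id = NULL, subclass = "IgG1") {
  n <- length(junction_aa)
  df <- data.frame(
    sequence_id = sprintf("S%03d", seq_len(n)),
    sequence = sequence %||% paste0("AAA", junction_aa, "TTT"),
    v_gene = rep_len(v_gene, n), j_gene = rep_len(j_gene, n),
    junction_aa = junction_aa, productive = TRUE,
    shm_count = rep_len(shm, n), rid_count = rep_len(rid_count, n),
    subclass = rep_len(subclass, n), stringsAsFactors = FALSE)
  if (!is.null(replicate_id)) df$replicate_id <- rep_len(replicate_id, n)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_aa <- function(n, len, alphabet = c("A", "C", "D", "E", "F", "G")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}
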