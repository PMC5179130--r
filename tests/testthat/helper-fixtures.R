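# Shared fixtures, all built in code.

# A tiny hand-written lineage set: two species in one genus, a second
# genus, and a column only classified to family.
tiny_lineages <- function() {
  parse_lineage(c(
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Staphylococcaceae;g__Staphylococcus;s__aureus",
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Staphylococcaceae;g__Staphylococcus;s__caprae",
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Enterococcaceae;g__Vagococcus;s__lutrae",
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Planococcaceae;g__;s__"))
}

tiny_count_table <- function(site = "ear") {
  counts <- rbind(S1 = c(3, 4, 2, 1),
                  S2 = c(0, 5, 5, 0),
                  S3 = c(1, 0, 9, 10))
  count_table(counts, tiny_lineages(), site = site)
}

# Random lineage-tagged count table for property tests.
random_count_table <- function(m = 6, n = 10, site = "ear", seed = 1) {
  set.seed(seed)
  lin <- generate_taxonomy(n, branching = 1.6)
  counts <- matrix(rpois(m * n, 12), m, n)
  counts[sample(length(counts), m)] <- 0
  count_table(counts, lin, site = site,
              sample_ids = sprintf("S%02d", seq_len(m)))
}

# Flat temperature series covering `days` days from `start`.
const_temps <- function(mean_c, start = "2015-06-01", days = 40) {
  data.frame(date = seq(as.Date(start), by = "day", length.out = days),
             mean_c = mean_c)
}

# Independent brute-force ADD oracle: enumerate half-day slots, each
# worth half its day's rate; clock runs death-midday to sample-midday.
oracle_add <- function(timeline, temps, sample_date, clamp_negative = TRUE) {
  days <- seq(timeline$death_date, as.Date(sample_date), by = "day")
  total <- 0
  for (day in as.list(days)) {
    for (half in c("am", "pm")) {
      if (day == timeline$death_date && half == "am") next
      if (day == as.Date(sample_date) && half == "pm") next
      frozen <- any(vapply(timeline$frozen_intervals,
                           function(iv) day >= iv[1] && day <= iv[2],
                           logical(1)))
      rate <- if (frozen) 0
      else if (day < timeline$placement_date ||
               (day == timeline$placement_date && half == "am")) {
        timeline$storage_temp_c
      } else {
        mc <- temps$mean_c[match(day, temps$date)]
        if (clamp_negative) max(mc, 0) else mc
      }
      total <- total + rate / 2
    }
  }
  total
}

# Small synthetic dataset shared by the slower protocol tests.
small_synthetic <- function(seed = 1, samples_per_cadaver = 8,
                            n_species = 60, depth = 5000, ...) {
  generate_dataset(synthetic_config(
    n_cadavers = 4, samples_per_cadaver = samples_per_cadaver,
    n_species = n_species, branching = 2, depth = depth, seed = seed, ...))
}
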