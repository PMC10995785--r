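#!/usr/bin/env Rscript
# Step 2 — aggregate and encode.
#
# Reads the simulated hourly records, aggregates them to daily ward- and
# room-level occupancy tables (checking the lossless round trip against the
# simulated states), derives the date features, and builds the three encoded
# dataset variants (ward / room / room+static) with min-max scaling fitted on
# the chronological training range only. Also prints the partition
# proportions of the entity-day rows.

library(borcast)
library(data.table)

data_dir <- "results/data"
layout <- readRDS(file.path(data_dir, "layout.rds"))
records <- read_bed_records(file.path(data_dir, "records.csv.gz"))
profiles <- read_static_profiles(file.path(data_dir, "static.csv"))
daily <- fread(file.path(data_dir, "daily_states.csv"))
holidays <- korean_holidays()

ward_tab <- aggregate_daily(records, layout, "ward", holidays)
room_tab <- aggregate_daily(records, layout, "room", holidays)

# lossless round trip: hourly aggregation must reproduce the simulated counts
chk <- merge(daily[, .(date = as.Date(date), room, occupied)],
             room_tab[, .(date, room = entity, occ2 = occupied)],
             by = c("date", "room"))
stopifnot(nrow(chk) == nrow(daily), identical(chk$occupied, chk$occ2))
cat("Round trip aggregate(expand(states)) == states: OK\n")

# the study's chronological partition boundaries
split <- split_spec(c("2020-05-27", "2021-12-31"),
                    c("2022-01-01", "2022-06-30"),
                    c("2022-07-01", "2022-11-21"))
counts <- sapply(list(split$train, split$validation, split$test), function(r)
  room_tab[date >= r[1] & date <= r[2], .N])
pct <- split_proportions(counts)
cat(sprintf("Room-day rows train/validation/test: %d/%d/%d (%.1f%% / %.1f%% / %.1f%%)\n",
            counts[1], counts[2], counts[3], pct[1], pct[2], pct[3]))

datasets <- list(
  ward = encode_and_normalize(ward_tab, "ward", train_range = split$train),
  room = encode_and_normalize(room_tab, "room", train_range = split$train),
  room_static = encode_and_normalize(room_tab, "room_static",
                                     static_profiles = profiles,
                                     train_range = split$train)
)

fwrite(ward_tab, file.path(data_dir, "ward_daily.csv"))
fwrite(room_tab, file.path(data_dir, "room_daily.csv"))
saveRDS(datasets, file.path(data_dir, "datasets.rds"))
saveRDS(split, file.path(data_dir, "split.rds"))
cat("Encoded dataset variants:", paste(names(datasets), collapse = ", "), "\n")
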