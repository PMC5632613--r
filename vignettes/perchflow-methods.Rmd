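---
title: "Gap-rule transformations of station detection streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-rule transformations of station detection streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perchflow)
```

## The data model

The atom of everything in `perchflow` is a *detection*: an opaque
animal id, an opaque station (logger) id, and a timestamp at
one-second precision, optionally georeferenced (WGS84 decimal
degrees) and carrying arbitrary metadata columns (species, sex,
experiment). RFID-enabled perches re-read a tag continuously while
the animal is in range, so the raw stream is massively redundant;
every derived quantity is produced by one of a family of *gap rules*
that segment the stream at different temporal scales:

| stage          | segments            | cutoff (`bw`)    | scale    |
|----------------|---------------------|------------------|----------|
| `visits()`     | reads → visits      | 3 s              | a perch sitting |
| `displacements()` | visit pairs → events | 2 s          | a supplant |
| `presence()`   | visits → bouts      | 15 min           | foraging around a station |
| `activity_grid()` | bouts → bins     | `res` = 15 min   | diel budget |

All four use one comparator, centralized in the code: **two events
merge (or pair) when the gap between them is strictly less than the
cutoff**. The strict inequality is a convention; the worked example
in the README is insensitive to it (its critical gaps are 2 s vs a
3 s cutoff and 12 s vs 3 s), but centralizing it guarantees the
boundary cannot differ between stages.

### Visits

Per animal, a maximal run of reads at one station with every
inter-read gap `< bw` becomes one visit (`start` = first read,
`end` = last read; a single read gives `start == end`). A station
change always terminates a visit, whatever the gap. Each call stamps
`animal_n`, the number of distinct animals in the input table, on
every row; per-individual averaging later divides by this number, so
it must be the population of the *source table* (or of the group,
under grouped application), not of any filtered subset.

The same animal read at two stations closer than `bw` seconds is
physically impossible (tag clone, clock skew). This is a hard error
by default: silently keeping either read would fabricate a movement
with a near-infinite strength. `allow_imp = TRUE` downgrades it to
drop-the-later-read with a warning, for users triaging dirty files.

### Displacements

Visits at one station are ordered by `(start, end, animal_id)` — the
animal-id tie-break makes simultaneous starts deterministic — and
each successive pair by different animals with `0 <= gap < bw` is an
event: arriving animal = displacer (winner), departing animal =
displacee (loser). The departing visit is the *most recently ended*
one; we do not require it to be ongoing at the arrival, since the
read stream cannot distinguish "still perched but unread for 1 s"
from "just left". `export_interactions()` emits the chronological
winner/loser sequence and the square winner-by-loser count matrix
(identical lexicographic animal order on both axes, zero diagonal)
that dominance packages consume.

### Movements

Consecutive visits by one animal at *different* stations form a
movement: departure at the earlier visit's end, arrival at the later
visit's start. The edge weight is the inverse of travel time
expressed per hour, `strength = 3600 / Δt_seconds`: a 4-minute hop
between neighbouring feeders weighs ~14.6, an overnight gap ~0.06.
No day-boundary logic exists anywhere — movements, bouts and gaps
span midnight naturally. `move_dir` is the directed
`"<from>_<to>"` label; `move_path` sorts the two station ids
ascending so both directions aggregate onto one undirected edge.
Zero travel time (arrival the same second as departure) leaves
strength undefined and errors, unless `allow_zero = TRUE` drops the
transition with a warning.

### Presence

Per animal, chronologically consecutive visits chain into a bout
while the end-to-start gap is `< bw` minutes and the station is
unchanged. A bout runs from its first visit's start to its **last
visit's end** — the length includes the within-bout gaps, which is
the point: presence measures time spent *around* a station, visits
measure time in read range. The "last visit's end" choice (rather
than its start) is deliberate: a bout's length should cover the whole
final visit; for an instantaneous final visit the two conventions
coincide.

### Activity

`activity_grid()` lays `res`-minute bins (default 15; `res` must
divide 1440 so bins tile the day) anchored at local midnight over
each animal's observed range — first bout start floored to the grid,
last bout end ceiled. A bin is active iff its **half-open** interval
`[t, t + res)` overlaps a bout; a bout ending exactly on a boundary
does not activate the next bin (no double counting), and an
instantaneous bout activates exactly the bin containing it. Trimming
the grid to the observed range means time before deployment or after
the last bout is *not* scored as inactivity. `daily_pattern()` then
averages per animal and time-of-day bin: `p_active` = active days /
days with a cell in that bin, with `n_days` reported. Days with no
cell in a bin are excluded from the denominator rather than counted
as inactive — scoring undeployed time as "inactive" would bias diel
patterns toward the deployment window. By default activity pools a
given animal's bouts across stations (activity is a property of the
animal); `by_logger = TRUE` gives station-level budgets.

## Loading and timestamps

Pre-labelled tables load via `load_format()`; raw per-station files
via `load_raw_file()`/`load_raw_all()`, which understand three
dialects (station id in the first line; id plus a `lat, lon` line;
id taken from the file name, optionally through a regular
expression) and three separators (whitespace runs, comma, semicolon).
A `logger_index()` CSV supplies coordinates by station id;
coordinates already present are kept unless `overwrite = TRUE` — the
precedence between a file's own coordinate header and an index is a
genuine ambiguity, so it is an explicit flag rather than a silent
rule. Stations missing from the index are reported, not errored.

Timestamp dialects are token-order strings over `y m d H M S p`
(e.g. `"dmy HM p"` for `31-12-17 09:12 pm`), handed to `lubridate`;
separators are flexible and two-digit years use the POSIX pivot
(00–68 → 2000s). Timezones are IANA names, default UTC. During DST
transitions, nonexistent spring-forward times fail to parse and are
reported with their row; ambiguous fall-back times resolve
deterministically to the standard-time (post-transition) offset.
Exact duplicate rows are kept by default (`dedup = TRUE` drops them);
duplicates within a second are consolidated by `visits()` anyway.
Written CSVs use local ISO 8601 `YYYY-MM-DD HH:MM:SS`, so a write →
read cycle under the same timezone is bit-stable to the second.

## Summaries, grouping, maps

`summarize_presence()` / `summarize_movements()` provide the four
summary modes: `sum` (total minutes per station / movement count per
path), `sum_indiv` (divided by `animal_n` — exactly, so
`sum_indiv × animal_n == sum` is an identity, tested as such),
`indiv` (per animal, optionally restricted via `which`), and `none`
(schema-validated pass-through for caller-precomputed summaries, the
path grouped workflows use). `apply_grouped()` splits any stage by
key columns (e.g. `experiment`), runs it independently per group and
re-attaches the keys: no visit, movement or bout ever spans two
groups, and `animal_n` is per group.

The map renderer is deliberately offline: nodes at station
coordinates sized and coloured by amount, straight segments between
path endpoints weighted and coloured by use, small black markers at
every station, a yellow→red ramp, equal-aspect latitude/longitude
axes, and an optional user-supplied background image with geographic
bounds. Tile-served basemaps are presentation, not computation, and
are out of scope. `scale_to_style()` maps amounts linearly onto a
display range (the original display scaling is unpublished; linear
is the least surprising choice and is exposed via `map_style()`),
with all-equal inputs sent to the range midpoint.

## The simulator

`simulate_detections()` emulates exactly the stream structure the
transformations assume: per animal, alternating bouts (1–5 visits of
2–8 reads at a 2 s read interval, within-bout gaps 5–300 s) and long
between-bout waits (20 min–4 h), with a 0.4 probability of switching
to another station between bouts, several animals interleaved at
four shared stations over a multi-day span. Those defaults were
chosen once as field-realistic for feeder passerines and are
validated as *guard bands*: the read interval sits strictly below
the visit cutoff, within-bout gaps strictly between the visit and
presence cutoffs, between-bout gaps strictly above the presence
cutoff — so the ground truth the generator records (visits, bouts,
movements) is recoverable *exactly*, for any seed, and recovery
tests assert equality, not approximation. Infeasible bands error at
configuration time. All times are whole seconds, matching logger
precision.

What the simulator does **not** emulate: dominance dynamics (no
engineered displacement structure), diel rhythms, tag read failures,
clock drift, or gaps that straddle a cutoff. Passing recovery tests
therefore shows the segmentation machinery is correct under
separable gaps; it says nothing about how a user should choose `bw`
when real gap distributions overlap a cutoff — that is a biological
decision, not a software one.

`emit_raw_files()` writes a table back out as per-station raw files
in any of the three dialects (month-first timestamps, as logger
firmware typically writes), which gives the loader a complete
round-trip test: simulate → emit → load must reproduce the table
bit-exactly.

## Testing strategy and problem sizes

Every transformation has an independent brute-force oracle in the
test helpers — plain nested loops sharing no code with the
implementations — and the suites compare them on randomized tables
(25 seeds per stage unit suite; a 500-table shakedown of up to 200
reads each in the end-to-end suite), alongside monotonicity checks
(visit and bout counts non-increasing in `bw`), conservation checks
(every read in exactly one visit, every visit in exactly one bout),
exact ground-truth recovery over 50 simulated one-day deployments of
two animals, and the `sum_indiv` scaling identity. The worked
single-finch example is asserted at printed precision: visit
boundaries to the second, movement strengths to two decimals
(3600/247 = 14.57, 3600/61218 = 0.06, 3600/6050 = 0.60 per hour),
bout lengths to six decimals (2.016667 and 11.700000 min). These
sizes keep the default suite comfortably under a few minutes on one
CPU while exercising every code path the larger deployments would.

## Known limitations

* Gap rules are hard thresholds; behaviour near a cutoff is
  all-or-nothing, and no uncertainty is propagated.
* Displacements are a proxy: a fast succession of two birds is not
  always a supplant, and true supplants slower than `bw` are missed.
* `strength` compresses travel time into a single inverse-hour
  number; it is a connectivity weight, not a speed estimate, and
  says nothing about the route taken.
* Presence assumes the animal stayed near the station between
  regular visits; an animal commuting rapidly elsewhere and back
  within `bw` minutes inflates presence.
* The loader trusts station clocks; no cross-logger clock
  reconciliation is attempted (impossible-read detection is the only
  guard).
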