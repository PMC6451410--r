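# erkchannel

Information transmission through pulse-interval codes in the MAPK/ERK
signalling pathway.

## The problem

The MAPK/ERK pathway converts epidermal growth factor (EGF) stimulation into
near-digital pulses of active (doubly phosphorylated) ERK. Read as an
amplitude code, the pathway carries only about one bit. This package is for
systems biologists who want to quantify the alternative: coding information
in the *timing* of short EGF pulses. An input is a binary sequence
`x ∈ {0,1}^L` of 5-min, 100 pg/ml pulses on a grid with base repeating time
`T`; the output is the vector of integrated single-cell ERK responses
`R_i = ∫ ERKpp(t) dt` over the successive windows, and the quantity of
interest is the mutual information MI(X; Y) and its maximum over input
distributions — the channel capacity, reported per hour as a bitrate.

The pathway is a relaxation oscillator with relaxation time `τ ≈ 51.5 min`:
after a full ERK pulse, pulses arriving within `τ` are absorbed. On a grid
with `kT < τ < (k+1)T` the noise-free channel acts as a deterministic
*refractory transcoding* (e.g. input `111` → response `101` at `T = 30`
min). Sequences with the same response form `K` groups; capacity is
`log2(K)`, the number of "accurately transmitted" sequences `n_L` follows
the Fibonacci-type recurrence `n_{L+1} = n_L + n_{L−k}`, and with slot
duration `T = 60/(k+1)` min the asymptotic capacity is

```
C(k) = (k + 1) · log2(a_k),   a_k the root in (1,2) of a^(k+1) = a^k + 1,
```

which *exceeds* the naive bandwidth limit of 1 bit per `τ`: ≈1.39 bit/h for
`T = 30` min and ≈1.86 bit/h for `T = 15` min.

The package implements the full analysis:

* exact combinatorics of refractory transcoding (groups, exact MI under
  canonical input schemes, recurrence asymptotics) — `transcode()`,
  `enumerate_groups()`, `exact_mi_partition()`, `asymptotic_bitrate()`;
* a calibrated ODE model of the pathway (positive feedback on SOS/RAS
  nested in a slow ERK→SOS negative feedback, RAF→MEK→ERK cascade) driven
  by EGF pulse protocols, with lognormal extrinsic noise —
  `simulate_mapk()`, `measure_relaxation_time()`, `sample_population()`;
* a fast surrogate stochastic channel for estimator validation —
  `generate_dataset()`;
* a weighted Kraskov-type kNN MI estimator for discrete inputs and
  continuous multi-dimensional responses, validated against a quadrature
  oracle — `estimate_mi()`, `mi_oracle_numeric()`;
* capacity maximization over the input distribution by Adam-style gradient
  ascent on a softmax parametrization — `maximize_mi()`;
* experiment drivers and plots — `run_mi_table()`, `run_two_pulse()`,
  `run_bitrate_scan()`, `run_fraction_responding()`, `plot_*()`.

## Worked example

Capacity of the noise-free four-pulse channel at `T = 30` min (`k = 1`), with
the optimizer run on 1000 simulated cells per input sequence:

```r
library(erkchannel)

theory_table(1:3)
#> # A tibble: 3 × 6
#>       k n_slots_per_hour T_min   a_k  a_k0 C_bit_per_h
#>   <int>            <int> <dbl> <dbl> <dbl>       <dbl>
#> 1     1                2    30  1.62  1.17        1.39
#> 2     2                3    20  1.47  1.31        1.65
#> 3     3                4    15  1.38  1.44        1.86

spec <- surrogate_spec(miss_width = 0, cell_cv = 0, mu0 = 0)  # noise-free
d <- generate_dataset(all_sequences(4), T_min = 30, spec = spec, M = 1000, seed = 1)
cap <- maximize_mi(d, knn = 15, seed = 2)
cap
#> Channel capacity estimate: C = 2.993 bits (uniform-input MI 2.871 bits)
#>   16 categories, knn = 15, 3 restart(s), converged: TRUE

group_mass(cap, enumerate_groups(4, 1))
#> # A tibble: 8 × 2
#>   representative  mass
#>   <chr>          <dbl>
#> 1 0000           0.124
#> 2 0001           0.124
#> 3 0010           0.125
#> # … 5 more rows, all ≈ 0.125
```

The estimated capacity matches the exact value `log2(8) = 3` bits (the 16
input sequences form 8 indistinguishable groups), the uniform-input MI
matches the exact `23/8 = 2.875` bits, and the optimizer distributes input
mass `1/8` over each group — the capacity-achieving distribution. Dividing
by the 2 h protocol duration, `bitrate(cap$C_bits, 4, 30)` ≈ 1.50 bit/h,
approaching the asymptotic `C = 1.39` bit/h from above as `L` grows (finite
sequences carry a boundary bonus; see `finite_L_mi()`).

The same machinery runs on the ODE backend
(`generate_dataset_ode()`, `backend = "ode"` in the drivers), where
`measure_relaxation_time(mapk_params())` recovers `τ` by bisection and
noise levels `sigma`/`mu0` control cell-to-cell variability and background
ERK activity.

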