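# protconn

Connectivity indicators for protected-area (PA) systems.

International biodiversity policy (e.g. Aichi Target 11 of the Convention
on Biological Diversity) asks countries not only to protect at least 17%
of their land but to do so through *well-connected* PA systems. This
package is for conservation scientists and indicator providers who need to
quantify that connectivity element: it measures what percent of a
country's land is both protected **and** reachable by dispersing
organisms, separates the causes of PA isolation, and turns the results
into per-country priority recommendations.

## The indicators

PAs are nodes of a spatial graph. Direct dispersal between PAs *i* and *j*
separated by edge-to-edge distance *d<sub>ij</sub>* follows a
negative-exponential kernel calibrated to the species' median dispersal
distance *d<sub>med</sub>*:

```
p_ij = 0.5^(d_ij / d_med)
```

Indirect movement is captured by the maximum-product path probability
*p\*<sub>ij</sub>*, and network connectivity by the Equivalent Connected
Area,

```
ECA = sqrt( Σ_i Σ_j  a_i · a_j · p*_ij )      [km²]
ProtConn = 100 · ECA / A_L                    [% of country land area A_L]
```

where the attribute *a* is the PA area for the country's own PAs and 0 for
*transboundary* PAs (foreign PAs within 500 km, which act only as stepping
stones). The family around ProtConn:

* **Prot** — PA coverage (% of land area).
* **ProtUnconn = Prot − ProtConn** — protected but isolated land,
  partitioned by cause into **ProtUnconn[Sea]** (isolation imposed by the
  sea), **ProtUnconn[Outland]** (unprotected foreign land separating the
  country's land portions) and **ProtUnconn[Design]** (limitations of the
  PA system itself).
* **ProtConn_Bound = Prot − ProtUnconn[Design]** — the connectivity the
  country is actually accountable for, with sea and foreign-land isolation
  factored out; always between ProtConn and Prot.
* The four **ProtConn fractions** (Within / Contig / Unprot / Trans, % of
  ProtConn) — how much of the connected land is reached within single PAs,
  across contiguous PAs, through unprotected national land, or via foreign
  protected stepping stones.
* A **priority classification** (A1, A2, B1, B2, B3, plus flag C) against
  the 17% target, from these indicators at the reference
  *d<sub>med</sub>* = 10 km.

## Worked example

A country made of two equal islands, each carrying one PA covering 10% of
the country (the `two_islands` preset, whose indicator values are known in
closed form):

```r
library(protconn)

sc  <- generate_scenario(preset_scenario("two_islands"))
ind <- compute_indicators(sc$pa_layer, sc$land_layer, d_med = c(10, 100))
ind[, c("iso3","d_med","prot","protconn","protconn_bound",
        "protunconn_sea","protunconn_outland","protunconn_design")]
#>   iso3 d_med prot protconn protconn_bound protunconn_sea protunconn_outland
#> 1  AAA    10   20    14.14             20          5.858                  0
#> 2  AAA   100   20    14.14             20          5.858                  0
#>   protunconn_design
#> 1                 0
#> 2                 0
```

Coverage is 20%, but because the two PAs can never reach each other across
the sea, only ProtConn = 100·2000·√2/20000 = 14.14% of the country is
protected *and* connected. The entire shortfall (5.86 points) is
attributed to the sea — the country's own design is blameless
(ProtUnconn[Design] = 0) — so ProtConn_Bound returns to 20% and the
country meets the 17% target:

```r
classify_priorities(ind, reference_dmed = 10)[, c("iso3","A1","A2","priority")]
#>   iso3    A1    A2 priority
#> 1  AAA FALSE FALSE        B
```

The same machinery runs on real layers (`read_geojson()` +
`compute_indicators()`), on Conefor-style plain-text node/connection files
(`read_conefor()` + `pa_network()`), or end to end with
`run_pipeline(run_config(...))`. A thin command-line interface with
`simulate / preprocess / network / indicators / classify / aggregate /
run` subcommands is installed under `inst/cli/protconn.R`.

## Further reading

See the methods vignette (`vignettes/protconn-methods.Rmd`) for the model
assumptions, the telescoping isolation partition, parameter defaults, the
synthetic-world generator's scope, and numerical choices.
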