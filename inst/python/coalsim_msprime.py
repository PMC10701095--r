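#!/usr/bin/env python
"""Coalescent simulation worker: reads a JSON demography/job spec, simulates
unlinked regions with msprime, writes an EIGENSTRAT (ASCII geno) triplet.

Spec keys: populations [{name, Ne}], splits [{time, ancestral, derived[]}],
pulses [{time, dest, source, proportion}] (forward-time semantics),
samples [{pop, n, pseudohaploid}], n_regions, region_length,
mutation_rate, recombination_rate, seed, out_prefix.
"""
import json
import sys

import msprime
import numpy as np


def build_demography(spec):
    dem = msprime.Demography()
    for p in spec["populations"]:
        dem.add_population(name=p["name"], initial_size=p["Ne"])
    events = []
    for s in spec["splits"]:
        events.append((float(s["time"]), "split", s))
    for p in spec["pulses"]:
        events.append((float(p["time_gen"]), "pulse", p))
    events.sort(key=lambda e: e[0])
    for t, kind, e in events:
        if kind == "split":
            dem.add_population_split(time=t, derived=list(e["derived"]),
                                     ancestral=e["ancestral"])
        else:
            # forward: dest receives proportion from source at t
            # backwards: lineages in dest move to source
            dem.add_mass_migration(time=t, source=e["dest"], dest=e["source"],
                                   proportion=float(e["proportion"]))
    dem.sort_events()
    return dem


def main(spec_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    dem = build_demography(spec)
    sample_sets = []
    col_meta = []  # (ind_id, pop, pseudohaploid) per output individual
    for s in spec["samples"]:
        ploidy = 1 if s["pseudohaploid"] else 2
        sample_sets.append(msprime.SampleSet(int(s["n"]), population=s["pop"],
                                             ploidy=ploidy,
                                             time=float(s.get("time_gen", 0))))
        for k in range(int(s["n"])):
            col_meta.append(("%s%d" % (s["pop"], k + 1), s["pop"],
                             bool(s["pseudohaploid"])))
    mu = float(spec["mutation_rate"])
    nreg = int(spec["n_regions"])
    rng = np.random.RandomState(int(spec["seed"]))
    anc_seeds = rng.randint(1, 2**31 - 1, size=nreg)
    mut_seeds = rng.randint(1, 2**31 - 1, size=nreg)
    reps = msprime.sim_ancestry(samples=sample_sets, demography=dem,
                                sequence_length=float(spec["region_length"]),
                                recombination_rate=float(spec["recombination_rate"]),
                                num_replicates=nreg,
                                random_seed=int(spec["seed"]))
    ploidies = []
    for s in spec["samples"]:
        ploidies += [1 if s["pseudohaploid"] else 2] * int(s["n"])
    geno_lines = []
    snp_rows = []
    digits = np.array(list("0123456789"))
    for r, ts in enumerate(reps):
        if mu <= 0:
            continue
        mts = msprime.sim_mutations(ts, rate=mu, random_seed=int(mut_seeds[r]),
                                    model=msprime.BinaryMutationModel())
        if mts.num_sites == 0:
            continue
        G = mts.genotype_matrix()          # sites x chromosomes, 0/1
        tot = G.sum(axis=1)
        seg = (tot > 0) & (tot < G.shape[1])
        if not seg.any():
            continue
        G = G[seg]
        pos = np.array([s.position for s in mts.sites()])[seg].astype(int)
        # collapse to per-individual genotype codes
        cols = []
        c = 0
        for pl in ploidies:
            if pl == 2:
                cols.append(G[:, c] + G[:, c + 1])
            else:
                cols.append(2 * G[:, c])   # pseudo-haploid: one chromosome
            c += pl
        M = np.stack(cols, axis=1)
        for i in range(M.shape[0]):
            geno_lines.append("".join(digits[M[i]]))
        for i, p in enumerate(pos):
            snp_rows.append((r + 1, int(p) + 1))
    out = spec["out_prefix"]
    with open(out + ".geno", "w") as fh:
        fh.write("\n".join(geno_lines))
        if geno_lines:
            fh.write("\n")
    with open(out + ".snp", "w") as fh:
        for k, (chrom, pos) in enumerate(snp_rows):
            # genetic position in Morgans at 1 cM/Mb
            fh.write("snp%d\t%d\t%.8f\t%d\tA\tC\n" % (k + 1, chrom, pos * 1e-8, pos))
    with open(out + ".ind", "w") as fh:
        for ind_id, pop, ph in col_meta:
            fh.write("%s\tU\t%s\t%s\n" % (ind_id, pop, "PH" if ph else "D"))
    print(len(snp_rows))


if __name__ == "__main__":
    main(sys.argv[1])
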