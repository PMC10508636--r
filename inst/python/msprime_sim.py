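"""Coalescent simulation driver.

Reads a JSON demographic model (populations with constant sizes, population
splits, admixture pulses, dated sample sets, genome specification), runs
msprime with a hybrid DTWF + coalescent model, and writes the polarized
diploid genotype matrix as Arrow/Feather tables (sites, calls, individuals).

Usage: python msprime_sim.py model.json out_dir
"""
import json
import math
import sys

import msprime
import numpy as np
import pyarrow as pa
import pyarrow.feather as feather


def build_demography(spec):
    d = msprime.Demography()
    for p in spec["populations"]:
        d.add_population(name=p["name"], initial_size=float(p["ne"]))
    for ev in spec["events"]:
        if ev["type"] == "split":
            d.add_population_split(time=float(ev["time"]),
                                   derived=list(ev["derived"]),
                                   ancestral=ev["ancestral"])
        elif ev["type"] == "pulse":
            # forward-time: `prop` of `recipient` ancestry comes from `donor`
            d.add_mass_migration(time=float(ev["time"]), source=ev["recipient"],
                                 dest=ev["donor"], proportion=float(ev["prop"]))
        else:
            raise ValueError("unknown event type: %s" % ev["type"])
    d.sort_events()
    return d


ALLELE_PAIRS = [("A", "G"), ("G", "A"), ("C", "T"), ("T", "C"),  # transitions
                ("A", "T"), ("T", "A"), ("C", "G"), ("G", "C"),  # AT/GC
                ("A", "C"), ("C", "A"), ("G", "T"), ("T", "G")]  # other tv
# transition:transversion = 2:1; transversion types uniform
PAIR_P = np.array([1 / 6.0] * 4 + [1 / 24.0] * 8)


def main(model_path, out_dir):
    spec = json.load(open(model_path))
    demog = build_demography(spec)
    genome = spec["genome"]
    n_chrom = int(genome["n_chrom"])
    length = float(genome["length"])
    window = float(genome.get("window", 250000))
    recomb = float(genome.get("recomb", 2e-8))
    mut = float(genome.get("mut", 1.25e-8))
    dtwf = float(spec.get("dtwf", 25))
    device = genome.get("device", "windows")
    samples = [msprime.SampleSet(int(s["n"]), population=s["pop"],
                                 time=float(s.get("time", 0)))
               for s in spec["samples"]]
    ids, pops = [], []
    for s in spec["samples"]:
        for i in range(int(s["n"])):
            ids.append("%s_%d" % (s["pop"], i + 1))
            pops.append(s["pop"])
    n_ind = len(ids)

    rng = np.random.default_rng(int(spec["seed"]))
    model = ([msprime.DiscreteTimeWrightFisher(duration=dtwf),
              msprime.StandardCoalescent()] if dtwf > 0 else "hudson")

    chrom_col, pos_col, dose_rows = [], [], []
    for ci in range(n_chrom):
        if device == "chromosome":
            spans = [(0.0, length)]
        else:
            nwin = max(1, int(math.ceil(length / window)))
            spans = [(w * window, min(length, (w + 1) * window))
                     for w in range(nwin)]
        for (lo, hi) in spans:
            seed1 = int(rng.integers(1, 2**31 - 1))
            seed2 = int(rng.integers(1, 2**31 - 1))
            ts = msprime.sim_ancestry(
                samples=samples, demography=demog, sequence_length=hi - lo,
                recombination_rate=recomb, random_seed=seed1, model=model)
            ts = msprime.sim_mutations(ts, rate=mut, random_seed=seed2,
                                       model=msprime.BinaryMutationModel())
            if ts.num_sites == 0:
                continue
            G = ts.genotype_matrix()  # sites x haploid samples, 0/1
            dose = (G[:, 0::2] + G[:, 1::2]).astype(np.int8)
            tot = dose.sum(axis=1)
            poly = (tot > 0) & (tot < 2 * n_ind)
            if not poly.any():
                continue
            pos = ts.tables.sites.position[poly].astype(np.int64) + int(lo) + 1
            dose = dose[poly]
            chrom_col.append(np.full(len(pos), ci + 1, dtype=np.int32))
            pos_col.append(pos)
            dose_rows.append(dose)

    if dose_rows:
        dose = np.concatenate(dose_rows, axis=0)
        chrom = np.concatenate(chrom_col)
        pos = np.concatenate(pos_col)
    else:
        dose = np.zeros((0, n_ind), dtype=np.int8)
        chrom = np.zeros(0, dtype=np.int32)
        pos = np.zeros(0, dtype=np.int64)

    pair_idx = rng.choice(len(ALLELE_PAIRS), size=len(pos), p=PAIR_P)
    anc = np.array([p[0] for p in ALLELE_PAIRS])[pair_idx]
    der = np.array([p[1] for p in ALLELE_PAIRS])[pair_idx]

    feather.write_feather(
        pa.table({"chrom": chrom, "pos": pos, "anc": anc, "der": der}),
        out_dir + "/sites.feather")
    feather.write_feather(
        pa.table({ids[j]: dose[:, j] for j in range(n_ind)}),
        out_dir + "/calls.feather")
    feather.write_feather(pa.table({"id": ids, "pop": pops}),
                          out_dir + "/ind.feather")
    json.dump({"n_sites": int(len(pos)), "n_ind": n_ind},
              open(out_dir + "/meta.json", "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
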