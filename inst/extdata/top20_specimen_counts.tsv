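latin_name	n_specimens
Rhododendron simsii	1435
Rhododendron decorum	1374
Rhododendron micranthum	826
Rhododendron mariesii	799
Rhododendron racemosum	630
Rhododendron oreodoxa	582
Rhododendron stamineum	573
Rhododendron ovatum	556
Rhododendron rubiginosum	488
Rhododendron pachytrichum	457
Rhododendron yunnanense	447
Rhododendron mariae	431
Rhododendron concinnum	391
Rhododendron microphyton	378
Rhododendron augustinii	376
Rhododendron vernicosum	374
Rhododendron siderophyllum	357
Rhododendron irroratum	342
Rhododendron mucronulatum	322
Rhododendron lutescens	320
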