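((Amborella,((Cabomba,Nymphaea),((Trimenia,Illicium),(((Chloranthus,Hedyosmum),((Magnolia,Liriodendron),Piper)),((Acorus,(Dioscorea,((Elaeis,Musa),(Oryza,Zea)))),(Ceratophyllum,(((Nandina,Ranunculus),(((Vitis,Leea),((Quercus,(Cucumis,(Fragaria,Populus))),(Arabidopsis,(Carica,(Gossypium,Eucalyptus))))),((Cornus,(Petalonyx,Hydrangea)),(Camellia,((Coffea,Solanum),Helianthus))))),(Nelumbo,(Sabia,(Platanus,Protea)))))))))),((Pinus,((Gnetum,Welwitschia),(Metasequoia,Sequoia))),(Ginkgo,(Cycas,Zamia))));
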